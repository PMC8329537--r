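#' Simulate a multi-generation cattle pedigree
#'
#' Founders (generation 1) are split evenly between sexes and assigned
#' farms, birth dates, and chip classes. In each later generation every dam
#' of the previous generation produces a Poisson-distributed number of
#' calves (at least one), sired by randomly drawn males of her generation;
#' calving ages follow the usual dairy pattern (first calving around 26
#' months, then roughly 13-month intervals), so maternal ages at birth span
#' the range used by the age analyses.
#'
#' @param config A [sim_config()] object; `n_generations` must be >= 3,
#'   otherwise no three-generation family can ever be observed.
#' @return A tibble with one row per animal: `animal_id`, `sire_id`,
#'   `dam_id`, `sex` (`"M"`/`"F"`), `birth_date` (Date), `farm_id`,
#'   `chip_class`, `generation`.
#' @export
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 12, seed = 7))
#' table(ped$generation)
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  if (config$n_generations < 3) {
    stop("n_generations must be >= 3: three-generation families are not ",
         "observable in a ", config$n_generations, "-generation pedigree",
         call. = FALSE)
  }
  set.seed(config$seed)

  farms <- sprintf("FARM%02d", seq_len(config$n_farms))
  chip_labels <- names(config$chip_classes)
  next_id <- 1L
  new_ids <- function(n) {
    ids <- sprintf("A%06d", seq(next_id, length.out = n))
    next_id <<- next_id + n
    ids
  }

  n_f <- config$n_founders
  founders <- tibble::tibble(
    animal_id = new_ids(n_f),
    sire_id = NA_character_,
    dam_id = NA_character_,
    sex = rep(c("F", "M"), length.out = n_f),
    birth_date = as.Date(sprintf("%d-01-01", config$start_year)) +
      sample.int(730L, n_f, replace = TRUE) - 1L,
    farm_id = sample(farms, n_f, replace = TRUE),
    chip_class = sample(chip_labels, n_f, replace = TRUE,
                        prob = config$chip_probs),
    generation = 1L
  )

  gens <- list(founders)
  for (g in 2:config$n_generations) {
    prev <- gens[[g - 1L]]
    dams <- prev[prev$sex == "F", ]
    sires <- prev[prev$sex == "M", ]
    if (nrow(dams) == 0L || nrow(sires) == 0L) break
    n_off <- pmax(1L, rpois(nrow(dams), config$mean_offspring_per_dam))
    rows <- purrr::map2(seq_len(nrow(dams)), n_off, function(i, k) {
      dam <- dams[i, ]
      # first calving ~26 mo, later calvings ~13 mo apart, in months
      ages <- cumsum(c(pmax(21, rnorm(1, 26, 3)),
                       pmax(11, rnorm(max(k - 1L, 0L), 13, 1.5))))[seq_len(k)]
      tibble::tibble(
        animal_id = NA_character_,
        sire_id = sample(sires$animal_id, k, replace = TRUE),
        dam_id = dam$animal_id,
        sex = sample(c("F", "M"), k, replace = TRUE),
        birth_date = dam$birth_date + round(ages * 30.4375),
        farm_id = ifelse(runif(k) < 0.9, dam$farm_id,
                         sample(farms, k, replace = TRUE)),
        chip_class = sample(chip_labels, k, replace = TRUE,
                            prob = config$chip_probs),
        generation = g
      )
    })
    gen <- dplyr::bind_rows(rows)
    gen$animal_id <- new_ids(nrow(gen))
    gens[[g]] <- gen
  }

  dplyr::bind_rows(gens)
}

#' Check a pedigree for cycles
#'
#' Depth-first search over parent -> offspring edges; a pedigree in which
#' some animal is its own ancestor is rejected with an error naming the
#' cycle.
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id`.
#' @return Invisibly `TRUE` if acyclic; otherwise an error.
#' @export
assert_pedigree_acyclic <- function(pedigree) {
  ids <- pedigree$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  parents <- lapply(seq_along(ids), function(i) {
    p <- c(pedigree$sire_id[i], pedigree$dam_id[i])
    unname(idx[p[!is.na(p) & p %in% ids]])
  })
  state <- integer(length(ids)) # 0 unvisited, 1 on stack, 2 done
  for (root in seq_along(ids)) {
    if (state[root] != 0L) next
    stack <- list(list(node = root, nexti = 1L))
    path <- root
    state[root] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$node]]
      if (top$nexti > length(ps)) {
        state[top$node] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$nexti <- top$nexti + 1L
      nb <- ps[top$nexti]
      if (state[nb] == 1L) {
        cyc <- c(ids[path[which(path == nb)[1]:length(path)]], ids[nb])
        stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "),
             call. = FALSE)
      }
      if (state[nb] == 0L) {
        state[nb] <- 1L
        path <- c(path, nb)
        stack[[length(stack) + 1L]] <- list(node = nb, nexti = 1L)
      }
    }
  }
  invisible(TRUE)
}
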