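#' Generate a complete synthetic dataset with truth tables
#'
#' Produces everything the analysis pipeline consumes, with known truth at
#' every stage: a multi-generation pedigree with birth dates, farms, and
#' chip classes; a marker map and fully phased genotypes obtained by
#' simulating every gamete (so offspring genotypes are Mendelian-exact
#' before error injection); a monthly farm temperature series; and, for
#' every maternal meiosis, the true genome-wide crossover count, the true
#' crossover positions, the latent rate, and the dam's additive genetic
#' value. Counts follow the latent-rate model of
#' [draw_crossover_count()] with marker-based genetic values scaled so the
#' GRM-REML estimand equals `h2_true` and the marginal count variance
#' equals `count_variance`.
#'
#' @param config A [sim_config()].
#' @return A list of class `recomb_bundle`: `config`, `pedigree`, `map`,
#'   `genotypes` (dosage matrix markers x animals, after error/missingness
#'   injection), `haplotypes` (list `paternal`, `maternal` of clean 0/1
#'   matrices), `temperature`, `meioses` (per-meiosis truth + covariates),
#'   `positions` (true crossover positions per meiosis), `genetic_values`
#'   (per-animal `g`), `variance_split`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  ped <- simulate_pedigree(config)
  map <- make_marker_map(config)
  yrs <- seq(min(lubridate::year(ped$birth_date)) - 1L,
             max(lubridate::year(ped$birth_date)))
  temps <- simulate_temperature(config,
                                farms = sprintf("FARM%02d",
                                                seq_len(config$n_farms)),
                                years = yrs)

  # meiosis plan: one maternal meiosis per offspring with a recorded dam
  plan <- ped[!is.na(ped$dam_id), c("animal_id", "dam_id", "sire_id")]
  names(plan)[1] <- "offspring_id"
  cov <- build_covariates(
    tibble::tibble(dam_id = plan$dam_id, offspring_id = plan$offspring_id),
    ped, temps)
  eta <- fixed_effect_eta(config, cov$A, cov$B, cov$T1, cov$T2)
  vs <- solve_variance_split(config, eta)

  set.seed(config$seed + 5L)
  n_animals <- nrow(ped)
  idx <- stats::setNames(seq_len(n_animals), ped$animal_id)
  m <- nrow(map)
  a <- rnorm(m, 0, sqrt(vs$sigma2_g / (2 * sum(map$maf * (1 - map$maf)))))

  H_pat <- matrix(NA_integer_, m, n_animals)
  H_mat <- matrix(NA_integer_, m, n_animals)
  founders <- which(is.na(ped$dam_id) & is.na(ped$sire_id))
  fh <- draw_founder_haplotypes(map, length(founders))
  H_pat[, founders] <- fh$h1
  H_mat[, founders] <- fh$h2

  genetic_value <- function(i) {
    sum(a * (H_pat[, i] + H_mat[, i] - 2 * map$maf))
  }

  non_founders <- which(!is.na(ped$dam_id))
  non_founders <- non_founders[order(ped$generation[non_founders])]
  meio <- vector("list", length(non_founders))
  pos <- vector("list", length(non_founders))
  cov_key <- stats::setNames(seq_len(nrow(cov)),
                             paste(cov$dam_id, cov$offspring_id))
  for (j in seq_along(non_founders)) {
    i <- non_founders[j]
    di <- idx[[ped$dam_id[i]]]
    si <- idx[[ped$sire_id[i]]]
    ci <- cov_key[[paste(ped$dam_id[i], ped$animal_id[i])]]
    g_dam <- genetic_value(di)
    lambda <- config$base_rate_mu + eta[ci] + g_dam +
      rnorm(1, 0, sqrt(vs$sigma2_lat))
    r_true <- draw_crossover_count(lambda, floor = config$count_floor)
    dam_gam <- simulate_meiosis(H_pat[, di], H_mat[, di], r_true, map)
    sire_gam <- simulate_meiosis(H_pat[, si], H_mat[, si],
                                 rpois(1, config$base_rate_mu), map)
    H_mat[, i] <- dam_gam$gamete
    H_pat[, i] <- sire_gam$gamete
    mid <- sprintf("%s|%s", ped$dam_id[i], ped$animal_id[i])
    meio[[j]] <- tibble::tibble(
      meiosis_id = mid, dam_id = ped$dam_id[i],
      offspring_id = ped$animal_id[i],
      R_true = r_true, lambda = lambda, g_dam = g_dam
    )
    if (nrow(dam_gam$positions)) {
      pos[[j]] <- dplyr::mutate(dam_gam$positions, meiosis_id = mid,
                                .before = 1)
    }
  }
  meioses <- dplyr::bind_rows(meio)
  meioses <- dplyr::left_join(
    meioses,
    dplyr::mutate(cov, meiosis_id = sprintf("%s|%s", cov$dam_id,
                                            cov$offspring_id)) |>
      dplyr::select("meiosis_id", "A", "B", "T1", "T2", "temp_complete"),
    by = "meiosis_id")

  geno <- H_pat + H_mat
  rownames(geno) <- map$marker_id
  colnames(geno) <- ped$animal_id
  geno <- inject_genotype_noise(geno, config$genotyping_error_rate,
                                config$missing_rate)

  g_all <- tibble::tibble(
    animal_id = ped$animal_id,
    g = vapply(seq_len(n_animals), genetic_value, numeric(1))
  )

  structure(list(
    config = config, pedigree = ped, map = map, genotypes = geno,
    haplotypes = list(paternal = H_pat, maternal = H_mat),
    temperature = temps, meioses = meioses,
    positions = dplyr::bind_rows(pos), genetic_values = g_all,
    variance_split = vs
  ), class = "recomb_bundle")
}

# Flip genotype calls to a different dosage with probability `error_rate`
# and blank them with probability `missing_rate`.
inject_genotype_noise <- function(geno, error_rate, missing_rate) {
  if (error_rate > 0) {
    flip <- which(runif(length(geno)) < error_rate)
    if (length(flip)) {
      shift <- sample(1:2, length(flip), replace = TRUE)
      geno[flip] <- (geno[flip] + shift) %% 3L
    }
  }
  if (missing_rate > 0) {
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  }
  geno
}

#' @export
print.recomb_bundle <- function(x, ...) {
  cat("<recomb_bundle>\n")
  cat(sprintf("  %d animals, %d markers on %d chromosomes, %d maternal meioses\n",
              nrow(x$pedigree), nrow(x$map),
              length(unique(x$map$chrom)), nrow(x$meioses)))
  cat(sprintf("  count mean %.2f / var %.2f (targets %.1f / %.1f)\n",
              mean(x$meioses$R_true), var(x$meioses$R_true),
              x$config$base_rate_mu, x$config$count_variance))
  invisible(x)
}
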