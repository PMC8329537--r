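#' Build a marker map for the simulated genome
#'
#' Markers are placed at sorted uniform physical positions on each
#' autosome; genetic position is linear in physical position, scaled so
#' each chromosome spans `map_length_morgans`. Coordinates are 0-based.
#'
#' @param config A [sim_config()].
#' @return A tibble `marker_id`, `chrom`, `pos` (0-based bp), `cm`
#'   (genetic position, Morgans), `ref`, `alt`, `maf` (founder allele
#'   frequency of the alt allele).
#' @export
make_marker_map <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  bases <- c("A", "C", "G", "T")
  purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    m <- config$markers_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp - 1L, m))
    ref <- sample(bases, m, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
    tibble::tibble(
      marker_id = sprintf("chr%d_%d", ch, pos),
      chrom = sprintf("chr%d", ch),
      pos = pos,
      cm = pos / config$chrom_length_bp * config$map_length_morgans,
      ref = ref,
      alt = alt,
      maf = runif(m, config$founder_maf[1], config$founder_maf[2])
    )
  })
}

#' Simulate one meiosis: gamete haplotype and true crossover positions
#'
#' Given the parent's two phased haplotypes, a genome-wide crossover
#' count, and the marker map, crossovers are allocated to chromosomes with
#' probability proportional to genetic map length and placed uniformly on
#' genetic distance (no interference). Each chromosome starts from a
#' random grandparental strand; the transmitted allele at every marker is
#' the allele of the currently active strand.
#'
#' @param hap1,hap2 Integer vectors of 0/1 alleles, one entry per row of
#'   `map` (strand 1 = grandpaternal, strand 2 = grandmaternal).
#' @param n_crossovers Non-negative genome-wide crossover count.
#' @param map Marker map from [make_marker_map()] (columns `chrom`, `pos`,
#'   `cm`).
#' @param chrom_lengths Optional named vector of genetic lengths per
#'   chromosome (Morgans); defaults to the span implied by `map` plus its
#'   leading offset.
#' @return A list: `gamete` (0/1 alleles), `origin` (1/2 active strand per
#'   marker), `positions` (tibble `chrom`, `pos_bp`, `pos_cm` of the true
#'   crossovers).
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chrom = 50, seed = 3)
#' map <- make_marker_map(cfg)
#' h1 <- rep(0L, nrow(map)); h2 <- rep(1L, nrow(map))
#' sim <- simulate_meiosis(h1, h2, 2L, map)
#' sum(diff(sim$origin) != 0) # 2 strand switches
simulate_meiosis <- function(hap1, hap2, n_crossovers, map,
                             chrom_lengths = NULL) {
  stopifnot(length(hap1) == nrow(map), length(hap2) == nrow(map))
  if (n_crossovers < 0) stop("n_crossovers must be >= 0", call. = FALSE)
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(map$cm[map$chrom == ch]),
                            numeric(1))
    names(chrom_lengths) <- chroms
  }
  alloc <- if (n_crossovers > 0) {
    as.integer(rmultinom(1, n_crossovers,
                         prob = chrom_lengths[chroms] / sum(chrom_lengths[chroms])))
  } else {
    integer(length(chroms))
  }
  origin <- integer(nrow(map))
  pos_list <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    sel <- which(map$chrom == ch)
    L <- chrom_lengths[[ch]]
    xo_cm <- sort(runif(alloc[i], 0, L))
    start <- sample(1:2, 1)
    # strand switches at each crossover, in genetic-map order
    n_before <- findInterval(map$cm[sel], xo_cm)
    origin[sel] <- 1L + (start - 1L + n_before) %% 2L
    pos_list[[i]] <- tibble::tibble(
      chrom = ch,
      pos_bp = xo_cm / L * max(map$pos[sel]),
      pos_cm = xo_cm
    )
  }
  gamete <- ifelse(origin == 1L, hap1, hap2)
  list(gamete = as.integer(gamete), origin = origin,
       positions = dplyr::bind_rows(pos_list))
}

#' Draw founder haplotypes
#'
#' One pair of haplotypes per founder, alleles Bernoulli at the map's
#' founder allele frequencies (linkage equilibrium).
#'
#' @param map Marker map with a `maf` column.
#' @param n Number of founders.
#' @return A list of two integer matrices (markers x founders).
#' @keywords internal
draw_founder_haplotypes <- function(map, n) {
  m <- nrow(map)
  h <- function() matrix(rbinom(m * n, 1L, rep(map$maf, n)), nrow = m)
  list(h1 = h(), h2 = h())
}
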