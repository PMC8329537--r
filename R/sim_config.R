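#' Simulation configuration
#'
#' Builds the configuration object consumed by every simulator in the
#' package. The defaults reproduce the statistical structure the analysis
#' assumes in US dairy cattle: a genome-wide maternal crossover count with
#' marginal mean 23.2 and variance 98.3, a heritability of 0.10 on the
#' count scale, a quadratic maternal-age effect, a linear-plus-quadratic
#' birth-year trend, and hot/cold temperature effects during the fetal
#' development of the offspring and of the parent. Genome size is desk
#' scale (5 chromosomes) with the per-chromosome genetic map length scaled
#' so that the expected genome-wide crossover count matches `base_rate_mu`.
#'
#' @param n_founders Number of founder animals (generation 1).
#' @param n_generations Total generations simulated; must be at least 3 so
#'   that three-generation families exist.
#' @param n_chromosomes Number of autosomes simulated.
#' @param markers_per_chrom SNP markers per chromosome.
#' @param chrom_length_bp Physical length of each chromosome in bp.
#' @param map_length_morgans Genetic length per chromosome (Morgans). The
#'   default `NULL` scales it to `base_rate_mu / n_chromosomes` so the map
#'   implies the configured expected genome-wide count.
#' @param founder_maf Range (min, max) of the uniform law for founder minor
#'   allele frequencies.
#' @param base_rate_mu Expected genome-wide crossovers per maternal meiosis.
#' @param count_variance Target marginal variance of the genome-wide count.
#' @param h2_true Fraction of count variance (after removing fixed-effect
#'   variance) that is additive-genetic; the estimand of the GRM-REML fit.
#' @param beta_age,beta_age2 Linear and quadratic maternal-age effects
#'   (crossovers per month, per month squared).
#' @param beta_birthyear,beta_birthyear2 Linear and quadratic parent
#'   birth-year effects (per calendar year, per year squared).
#' @param beta_hot,beta_cold Effects of a hot / cold month preceding the
#'   offspring's birth (fetal development of the offspring).
#' @param beta_hot_parent,beta_cold_parent Effects of a hot / cold month
#'   preceding the parent's own birth (fetal development of the parent).
#' @param seasonal_temp Named vector `c(mean, amplitude, noise_sd)` in
#'   degrees Celsius describing the sinusoidal annual temperature cycle.
#' @param farm_temp_sd Between-farm standard deviation of the annual mean
#'   temperature (degrees Celsius).
#' @param n_farms Number of farms.
#' @param start_year First founder birth year.
#' @param mean_offspring_per_dam Average number of calves per dam per
#'   generation step.
#' @param chip_classes Named integer vector mapping chip-class labels to
#'   marker counts, used by the panel-density filter.
#' @param chip_probs Sampling probabilities of `chip_classes` per animal.
#' @param genotyping_error_rate Per-call probability that a genotype is
#'   replaced by a different dosage.
#' @param missing_rate Per-call probability that a genotype is missing.
#' @param count_floor Lower floor applied to the latent Poisson rate.
#' @param seed Integer seed; every simulator derives its stream from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 20, seed = 1)
#' cfg$base_rate_mu
sim_config <- function(n_founders = 80,
                       n_generations = 4,
                       n_chromosomes = 5,
                       markers_per_chrom = 400,
                       chrom_length_bp = 1e8,
                       map_length_morgans = NULL,
                       founder_maf = c(0.05, 0.5),
                       base_rate_mu = 23.2,
                       count_variance = 98.3,
                       h2_true = 0.10,
                       beta_age = -0.082,
                       beta_age2 = 4.69e-4,
                       beta_birthyear = 5.02e-3,
                       beta_birthyear2 = -4.41e-7,
                       beta_hot = 0.167,
                       beta_cold = -0.194,
                       beta_hot_parent = 0.093,
                       beta_cold_parent = 0.139,
                       seasonal_temp = c(mean = 12, amplitude = 15, noise_sd = 2),
                       farm_temp_sd = 3,
                       n_farms = 6,
                       start_year = 2000,
                       mean_offspring_per_dam = 3,
                       chip_classes = c("GGP-7K" = 6909L, "GGP-50K" = 54609L,
                                        "HD-777K" = 777962L),
                       chip_probs = c(0.08, 0.72, 0.20),
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.005,
                       count_floor = 0.5,
                       seed = 2026L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chrom = as.integer(markers_per_chrom),
    chrom_length_bp = chrom_length_bp,
    map_length_morgans = if (is.null(map_length_morgans))
      base_rate_mu / n_chromosomes else map_length_morgans,
    founder_maf = founder_maf,
    base_rate_mu = base_rate_mu,
    count_variance = count_variance,
    h2_true = h2_true,
    beta_age = beta_age, beta_age2 = beta_age2,
    beta_birthyear = beta_birthyear, beta_birthyear2 = beta_birthyear2,
    beta_hot = beta_hot, beta_cold = beta_cold,
    beta_hot_parent = beta_hot_parent, beta_cold_parent = beta_cold_parent,
    seasonal_temp = seasonal_temp,
    farm_temp_sd = farm_temp_sd,
    n_farms = as.integer(n_farms),
    start_year = as.integer(start_year),
    mean_offspring_per_dam = mean_offspring_per_dam,
    chip_classes = chip_classes,
    chip_probs = chip_probs,
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    count_floor = count_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(n_founders = cfg$n_founders, n_generations = cfg$n_generations,
              n_chromosomes = cfg$n_chromosomes,
              markers_per_chrom = cfg$markers_per_chrom,
              n_farms = cfg$n_farms)
  if (any(counts <= 0)) {
    stop("sim_config counts must all be positive: ",
         paste(names(counts)[counts <= 0], collapse = ", "), call. = FALSE)
  }
  if (cfg$h2_true < 0 || cfg$h2_true > 1) {
    stop("h2_true must lie in [0, 1]", call. = FALSE)
  }
  probs <- c(genotyping_error_rate = cfg$genotyping_error_rate,
             missing_rate = cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (cfg$map_length_morgans <= 0) {
    stop("map_length_morgans must be positive", call. = FALSE)
  }
  if (length(cfg$founder_maf) != 2 || any(cfg$founder_maf <= 0) ||
      any(cfg$founder_maf > 0.5) || cfg$founder_maf[1] > cfg$founder_maf[2]) {
    stop("founder_maf must be an increasing pair in (0, 0.5]", call. = FALSE)
  }
  if (length(cfg$chip_classes) != length(cfg$chip_probs)) {
    stop("chip_classes and chip_probs must have equal length", call. = FALSE)
  }
  if (cfg$base_rate_mu <= 0 || cfg$count_variance <= 0) {
    stop("base_rate_mu and count_variance must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  pedigree: %d founders, %d generations, %d farms\n",
              x$n_founders, x$n_generations, x$n_farms))
  cat(sprintf("  genome:   %d chromosomes x %d markers, %.2f M each\n",
              x$n_chromosomes, x$markers_per_chrom, x$map_length_morgans))
  cat(sprintf("  counts:   mu = %.1f, target variance = %.1f, h2 = %.2f\n",
              x$base_rate_mu, x$count_variance, x$h2_true))
  invisible(x)
}
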