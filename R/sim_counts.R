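#' Draw genome-wide crossover counts from the latent-rate model
#'
#' Counts are Poisson conditional on a meiosis-specific latent rate
#' \eqn{\lambda_i = \mu + x_i'\beta + g_i + e_i}; the caller supplies the
#' assembled rate. Rates are floored at a small positive value so the
#' Poisson draw is always defined; any Gaussian latent variance makes the
#' marginal count distribution overdispersed (variance = E\eqn{\lambda} +
#' var\eqn{\lambda} by the law of total variance).
#'
#' @param lambda Numeric vector of latent expected rates, one per meiosis.
#' @param floor Lower floor applied to `lambda` (default 0.5).
#' @return Integer vector of crossover counts.
#' @export
#' @examples
#' mean(draw_crossover_count(rep(23.2, 1000)))
draw_crossover_count <- function(lambda, floor = 0.5) {
  rpois(length(lambda), pmax(lambda, floor))
}

#' Solve the latent variance split for a covariate set
#'
#' Given the realized (centered) fixed-effect contribution to the latent
#' rate, splits the configured marginal count variance into an
#' additive-genetic part and a meiosis-level latent residual so that (i)
#' the marginal count variance equals `count_variance` and (ii) `h2_true`
#' is exactly the estimand of a GRM-REML fit on the counts:
#' `sigma2_g = h2 (V - v_f)`, `sigma2_lat = (1 - h2)(V - v_f) - mu`
#' (the Poisson noise `mu` lands in the model residual).
#'
#' @param config A [sim_config()].
#' @param eta Numeric vector of centered fixed-effect contributions.
#' @return List `sigma2_g`, `sigma2_lat`, `var_fixed`.
#' @keywords internal
solve_variance_split <- function(config, eta) {
  var_fixed <- if (length(eta) > 1) var(eta) else 0
  avail <- config$count_variance - var_fixed
  sigma2_g <- config$h2_true * avail
  sigma2_lat <- (1 - config$h2_true) * avail - config$base_rate_mu
  if (sigma2_lat < 0) {
    stop("count_variance too small for base_rate_mu + fixed effects: ",
         "latent residual variance would be negative", call. = FALSE)
  }
  list(sigma2_g = sigma2_g, sigma2_lat = sigma2_lat, var_fixed = var_fixed)
}

# Centered fixed-effect contribution of the model covariates to the rate.
fixed_effect_eta <- function(config, A, B, T1, T2) {
  eta <- config$beta_age * A + config$beta_age2 * A^2 +
    config$beta_birthyear * B + config$beta_birthyear2 * B^2
  if (!is.null(T1)) {
    eta <- eta + config$beta_hot * (T1 == "hot") +
      config$beta_cold * (T1 == "cold")
  }
  if (!is.null(T2)) {
    eta <- eta + config$beta_hot_parent * (T2 == "hot") +
      config$beta_cold_parent * (T2 == "cold")
  }
  eta - mean(eta)
}

#' Simulate per-meiosis phenotypes with marker-based genetic values
#'
#' The fast phenotype-level simulator: dams get independent SNP dosages
#' (for the GRM) and an additive genetic value built from marker effects,
#' each dam contributes `meioses_per_dam` meioses with realistic calving
#' ages, birth years, and farm temperature categories, and genome-wide
#' crossover counts are drawn from the latent-rate model. Used for
#' calibration and parameter-recovery experiments where full genotype
#' transmission is not needed.
#'
#' @param config A [sim_config()]; effect sizes, `base_rate_mu`,
#'   `count_variance`, and `h2_true` are taken from it.
#' @param n_dams Number of dams (parents).
#' @param meioses_per_dam Meioses observed per dam.
#' @param n_markers Markers used for the genetic values / GRM.
#' @return A tibble with one row per meiosis (`dam_id`, `R`, `A`, `B`,
#'   `T1`, `T2`, `lambda`, `g`, `chip_class`, `informative_n`) carrying
#'   attributes `dosages` (dams x markers), `truth` (the variance split
#'   used), and `config`.
#' @export
simulate_meiosis_phenotypes <- function(config, n_dams = 500,
                                        meioses_per_dam = 4,
                                        n_markers = 800) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  k <- meioses_per_dam
  n <- n_dams * k

  # dam covariates: birth year/date, farm; per-meiosis calving ages
  farms <- sprintf("FARM%02d", seq_len(config$n_farms))
  dam_id <- sprintf("D%05d", seq_len(n_dams))
  dam_birth <- as.Date(sprintf("%d-01-01", config$start_year)) +
    sample.int(3652L, n_dams, replace = TRUE)
  dam_farm <- sample(farms, n_dams, replace = TRUE)
  ages <- t(apply(matrix(0, n_dams, k), 1, function(z) {
    cumsum(c(pmax(21, rnorm(1, 26, 3)), pmax(11, rnorm(k - 1, 13, 1.5)))[seq_len(k)])
  }))
  if (k == 1) ages <- matrix(ages, ncol = 1)

  df <- tibble::tibble(
    dam_id = rep(dam_id, each = k),
    dam_birth = rep(dam_birth, each = k),
    farm_id = rep(dam_farm, each = k),
    A = as.integer(round(as.vector(t(ages))))
  )
  df$off_birth <- df$dam_birth + round(df$A * 30.4375)
  df$B <- lubridate::year(df$dam_birth)

  yrs <- seq(min(lubridate::year(df$dam_birth)) - 1L,
             max(lubridate::year(df$off_birth)))
  temps <- simulate_temperature(config, farms = farms, years = yrs)
  df$T1 <- categorize_temperature(temp_month_prior(temps, df$off_birth,
                                                   df$farm_id))
  df$T2 <- categorize_temperature(temp_month_prior(temps, df$dam_birth,
                                                   df$farm_id))

  set.seed(config$seed + 4L)
  # genetics: iid dosages, VanRaden-scaled marker effects => cov(g) = sg2 * G
  p <- runif(n_markers, config$founder_maf[1], config$founder_maf[2])
  M <- matrix(rbinom(n_dams * n_markers, 2L, rep(p, each = n_dams)),
              nrow = n_dams)
  rownames(M) <- dam_id
  eta <- fixed_effect_eta(config, df$A, df$B, df$T1, df$T2)
  vs <- solve_variance_split(config, eta)
  phat <- colMeans(M) / 2
  denom <- 2 * sum(phat * (1 - phat))
  a <- rnorm(n_markers, 0, sqrt(vs$sigma2_g / denom))
  g_dam <- as.vector(sweep(M, 2, 2 * phat) %*% a)
  df$g <- rep(g_dam, each = k)

  df$lambda <- config$base_rate_mu + eta + df$g +
    rnorm(n, 0, sqrt(vs$sigma2_lat))
  df$R <- draw_crossover_count(df$lambda, floor = config$count_floor)
  df$chip_class <- names(config$chip_classes)[
    which.max(config$chip_classes >= 5e4)]
  df$informative_n <- n_markers
  df$offspring_id <- sprintf("%s_m%d", df$dam_id, rep(seq_len(k), n_dams))

  out <- dplyr::select(df, "dam_id", "offspring_id", "R", "A", "B",
                       "T1", "T2", "lambda", "g", "chip_class",
                       "informative_n")
  attr(out, "dosages") <- M
  attr(out, "truth") <- vs
  attr(out, "config") <- config
  out
}
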