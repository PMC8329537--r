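#' Simulate monthly farm temperature series
#'
#' Emulates a NOAA-GHCN-style table of monthly average temperatures per
#' station (one station per farm): a sinusoidal annual cycle peaking in
#' July (month 7) and bottoming in January, a farm-specific shift of the
#' annual mean, and independent month-to-month noise,
#' \deqn{T_{f,m} = \bar T + \delta_f + a\,\cos(2\pi (m - 7)/12) + \epsilon.}
#'
#' @param config A [sim_config()]; `seasonal_temp = c(mean, amplitude,
#'   noise_sd)` in degrees Celsius and `farm_temp_sd` control the series.
#' @param farms Character vector of farm ids; defaults to the ids
#'   [simulate_pedigree()] assigns.
#' @param years Integer vector of calendar years to cover.
#' @return A tibble `farm_id`, `year`, `month`, `tavg_c`, one row per
#'   (farm, calendar month).
#' @export
#' @examples
#' cfg <- sim_config(seasonal_temp = c(mean = 15, amplitude = 0, noise_sd = 0),
#'                   farm_temp_sd = 0)
#' simulate_temperature(cfg, farms = "FARM01", years = 2001)
simulate_temperature <- function(config,
                                 farms = sprintf("FARM%02d",
                                                 seq_len(config$n_farms)),
                                 years = config$start_year +
                                   seq(-1L, 3L * config$n_generations)) {
  validate_sim_config(config)
  st <- config$seasonal_temp
  if (length(st) != 3) stop("seasonal_temp must be c(mean, amplitude, noise_sd)")
  set.seed(config$seed + 1L)
  offsets <- stats::setNames(rnorm(length(farms), 0, config$farm_temp_sd), farms)
  grid <- tidyr::expand_grid(farm_id = farms, year = as.integer(years),
                             month = 1:12)
  grid$tavg_c <- st[[1]] + unname(offsets[grid$farm_id]) +
    st[[2]] * cos(2 * pi * (grid$month - 7) / 12) +
    rnorm(nrow(grid), 0, st[[3]])
  grid
}
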