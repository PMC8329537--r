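#' Maternal age in complete months
#'
#' Number of whole calendar months between the parent's and the
#' offspring's birth dates (floor).
#'
#' @param parent_birth,offspring_birth Dates (or strings coercible to
#'   Date); vectorized.
#' @return Integer vector of complete months.
#' @export
#' @examples
#' maternal_age_months(as.Date("2010-01-01"), as.Date("2014-06-01")) # 53
maternal_age_months <- function(parent_birth, offspring_birth) {
  parent_birth <- as.Date(parent_birth)
  offspring_birth <- as.Date(offspring_birth)
  if (any(offspring_birth < parent_birth, na.rm = TRUE)) {
    stop("offspring born before parent", call. = FALSE)
  }
  mm <- 12L * (lubridate::year(offspring_birth) - lubridate::year(parent_birth)) +
    (lubridate::month(offspring_birth) - lubridate::month(parent_birth))
  as.integer(mm - (lubridate::day(offspring_birth) < lubridate::day(parent_birth)))
}

#' Average temperature of the month prior to a birth date
#'
#' Looks up, in a monthly temperature series, the stored average for the
#' calendar month immediately preceding the birth month at the animal's
#' farm. Missing months yield `NA` (the record is flagged for exclusion
#' from temperature analyses, not an error).
#'
#' @param series Tibble `farm_id`, `year`, `month`, `tavg_c` (one row per
#'   farm-month), as written by [simulate_temperature()].
#' @param birth_date Date vector.
#' @param farm_id Farm id vector, recycled against `birth_date`.
#' @return Numeric vector of temperatures (degrees Celsius), `NA` where the
#'   required month is absent from the series.
#' @export
#' @examples
#' s <- tibble::tibble(farm_id = "F1", year = 2015, month = 5, tavg_c = 20)
#' temp_month_prior(s, as.Date("2015-06-15"), "F1") # 20
temp_month_prior <- function(series, birth_date, farm_id) {
  birth_date <- as.Date(birth_date)
  y <- lubridate::year(birth_date)
  m <- lubridate::month(birth_date)
  prior_y <- ifelse(m == 1, y - 1, y)
  prior_m <- ifelse(m == 1, 12, m - 1)
  key <- paste(farm_id, prior_y, prior_m, sep = "|")
  lut <- stats::setNames(series$tavg_c,
                         paste(series$farm_id, series$year, series$month,
                               sep = "|"))
  unname(lut[key])
}

#' Categorize a temperature as cold, normal, or hot
#'
#' Fixed thresholds used throughout: hot strictly above `hot` (default
#' 26.67 degrees C), cold strictly below `cold` (default 4.44 degrees C),
#' otherwise normal; boundary values are normal.
#'
#' @param t Numeric temperatures (degrees Celsius). `NA` propagates.
#' @param hot,cold Category thresholds.
#' @return Factor with levels `cold`, `normal`, `hot`.
#' @export
#' @examples
#' categorize_temperature(c(30, 0, 26.67))
categorize_temperature <- function(t, hot = 26.67, cold = 4.44) {
  if (any(is.infinite(t) | is.nan(t))) {
    stop("temperatures must be finite", call. = FALSE)
  }
  out <- ifelse(t > hot, "hot", ifelse(t < cold, "cold", "normal"))
  factor(out, levels = c("cold", "normal", "hot"))
}

#' Assign a maternal-age group
#'
#' Ten groups from 20 months with an increment of 10 months:
#' `[20,30), [30,40), ..., [110, Inf)`; the last group collects all
#' records of parents giving birth over 120 months. Ages below 20 months
#' are returned as `NA` (excluded from grouped displays).
#'
#' @param age_months Numeric vector of maternal ages in months.
#' @return Integer group 1..10, `NA` below 20 months.
#' @export
#' @examples
#' age_group(c(23, 65, 127)) # 1, 5, 10
age_group <- function(age_months) {
  g <- pmin(10L, as.integer(floor((age_months - 20) / 10)) + 1L)
  g[age_months < 20] <- NA_integer_
  g
}

#' Residualize crossover counts on chip density and informative markers
#'
#' The recombination phenotype used downstream is the residual `Y` of the
#' genome-wide crossover count `R` after a least-squares adjustment for
#' SNP-chip class (categorical) and the number of informative markers
#' (continuous). With a single chip class and constant informative count
#' this reduces to centering `R`.
#'
#' @param records Tibble with columns `R`, `chip_class`, and
#'   `informative_n`.
#' @return `records` with an added column `Y` (the residual phenotype).
#' @export
adjust_rate <- function(records) {
  if (nrow(records) < 2) {
    stop("adjust_rate needs at least 2 records (singular design)",
         call. = FALSE)
  }
  cls <- factor(records$chip_class)
  terms <- character(0)
  if (nlevels(droplevels(cls)) > 1) terms <- c(terms, "chip_class")
  if (length(unique(records$informative_n)) > 1) {
    terms <- c(terms, "informative_n")
  }
  fml <- stats::reformulate(if (length(terms)) terms else "1", response = "R")
  fit <- lm(fml, data = records)
  dplyr::mutate(records, Y = unname(residuals(fit)))
}

#' Build the analysis-ready covariate table for maternal meioses
#'
#' Joins per-meiosis crossover records with the pedigree and the monthly
#' temperature series to produce one row per meiosis carrying the model
#' covariates: maternal age `A` (complete months), parent birth year `B`,
#' and the temperature categories `T1` (month prior to the offspring's
#' birth, fetal development of the offspring) and `T2` (month prior to the
#' parent's own birth, fetal development of the parent). Records whose
#' required temperature month is missing keep `NA` categories and are
#' flagged via `temp_complete`.
#'
#' @param records Tibble with `dam_id`, `offspring_id` (and typically `R`,
#'   `informative_n`, `chip_class`).
#' @param pedigree Pedigree tibble with `animal_id`, `birth_date`,
#'   `farm_id`.
#' @param temperature Monthly series as in [temp_month_prior()], or `NULL`
#'   to skip the temperature covariates.
#' @param hot,cold Category thresholds passed to
#'   [categorize_temperature()].
#' @return `records` with added columns `A`, `B`, `T1`, `T2`,
#'   `temp_complete`.
#' @export
build_covariates <- function(records, pedigree, temperature = NULL,
                             hot = 26.67, cold = 4.44) {
  ped <- dplyr::select(pedigree, "animal_id", "birth_date", "farm_id")
  out <- records |>
    dplyr::left_join(ped, by = c("dam_id" = "animal_id")) |>
    dplyr::rename(dam_birth = "birth_date", dam_farm = "farm_id") |>
    dplyr::left_join(ped, by = c("offspring_id" = "animal_id")) |>
    dplyr::rename(off_birth = "birth_date", off_farm = "farm_id")
  out$A <- maternal_age_months(out$dam_birth, out$off_birth)
  out$B <- lubridate::year(out$dam_birth)
  if (!is.null(temperature)) {
    t1 <- temp_month_prior(temperature, out$off_birth, out$off_farm)
    t2 <- temp_month_prior(temperature, out$dam_birth, out$dam_farm)
    out$T1 <- categorize_temperature(t1, hot = hot, cold = cold)
    out$T2 <- categorize_temperature(t2, hot = hot, cold = cold)
    out$temp_complete <- !is.na(t1) & !is.na(t2)
  } else {
    out$T1 <- out$T2 <- factor(NA, levels = c("cold", "normal", "hot"))
    out$temp_complete <- FALSE
  }
  dplyr::select(out, -"dam_birth", -"dam_farm", -"off_birth", -"off_farm")
}
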