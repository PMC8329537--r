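#' Smooth-spline fit of recombination residuals on maternal age
#'
#' Cubic smoothing spline of the residual phenotype on maternal age with
#' generalized cross-validated smoothing, evaluated on an age grid; also
#' reports the age minimizing the fitted curve (the turning point of the
#' U-shaped maternal-age trend).
#'
#' @param Y Numeric residual phenotype.
#' @param A Maternal ages (months); at least 10 distinct values.
#' @param grid_n Grid resolution.
#' @return Object of class `recomb_spline`: list with `grid` (tibble
#'   `age`, `fitted`), `argmin_age`, and the underlying
#'   [stats::smooth.spline] fit.
#' @export
fit_age_spline <- function(Y, A, grid_n = 400) {
  ok <- is.finite(Y) & is.finite(A)
  Y <- Y[ok]; A <- A[ok]
  if (length(unique(A)) < 2) stop("maternal age is constant", call. = FALSE)
  if (length(unique(A)) < 10) {
    stop("fit_age_spline needs >= 10 distinct ages", call. = FALSE)
  }
  sp <- smooth.spline(A, Y, cv = FALSE)
  grid <- seq(min(A), max(A), length.out = grid_n)
  fitted <- predict(sp, grid)$y
  structure(list(
    grid = tibble::tibble(age = grid, fitted = fitted),
    argmin_age = grid[which.min(fitted)],
    spline = sp
  ), class = "recomb_spline")
}

#' @export
print.recomb_spline <- function(x, ...) {
  cat(sprintf("<recomb_spline> GCV smoothing spline, argmin at %.1f months\n",
              x$argmin_age))
  invisible(x)
}

#' Per-group mean and standard error
#'
#' Summary used for the age-group dot-and-bar display: per group `n`,
#' mean, and standard error of the mean (`sd / sqrt(n)`). Factor groups
#' with no observations are reported with `n = 0` and undefined mean.
#'
#' @param Y Numeric values.
#' @param groups Group labels (factor levels are preserved, including
#'   empty ones).
#' @return Tibble `group`, `n`, `mean`, `se`.
#' @export
#' @examples
#' group_summary(c(2, 4), c("g1", "g1"))
group_summary <- function(Y, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  out <- tibble::tibble(Y = Y, group = groups) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = ifelse(dplyr::n() > 0, mean(.data$Y), NA_real_),
      se = ifelse(dplyr::n() > 1, sd(.data$Y) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
  out
}

#' Boxplot statistics of residuals per temperature category
#'
#' Per observed category: `n`, mean, median, quartiles, and whiskers by
#' the 1.5 x IQR rule (via [grDevices::boxplot.stats]). Categories with no
#' observations are omitted with a warning.
#'
#' @param Y Numeric residual phenotype.
#' @param category Temperature category factor (cold/normal/hot).
#' @return Tibble `category`, `n`, `mean`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`.
#' @export
temp_group_summary <- function(Y, category) {
  category <- factor(category, levels = union(c("cold", "normal", "hot"),
                                              levels(factor(category))))
  keep <- !is.na(category) & is.finite(Y)
  Y <- Y[keep]; category <- category[keep]
  absent <- setdiff(levels(category), as.character(unique(category)))
  if (length(absent)) {
    warning("temperature categor", if (length(absent) > 1) "ies" else "y",
            " absent from data: ", paste(absent, collapse = ", "))
  }
  purrr::map_dfr(intersect(levels(category), as.character(unique(category))),
                 function(lev) {
    y <- Y[category == lev]
    bs <- grDevices::boxplot.stats(y)$stats
    tibble::tibble(category = lev, n = length(y), mean = mean(y),
                   median = bs[3], q1 = bs[2], q3 = bs[4],
                   whisker_low = bs[1], whisker_high = bs[5])
  })
}
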