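#' Fit the full recombination-rate mixed model
#'
#' Fits, by exact REML, the model
#' \deqn{Y = \alpha + T_1 + T_2 + A + A^2 + B + B^2 + g + \epsilon,}
#' where `Y` is the residualized crossover count, `T1`/`T2` are the
#' three-level temperature categories during the fetal development of the
#' offspring and of the parent (normal is the reference level), `A` is
#' maternal age in months, `B` the parent's birth year (both uncentered in
#' the reported coefficients), and `g` is a per-parent additive genetic
#' effect with covariance `sigma2_g * G` shared across that parent's
#' meioses. Internally the quadratic covariates are centered before
#' fitting (for conditioning) and estimates are mapped back to the raw
#' scale, covariances included. Fixed effects get GLS estimates with
#' standard errors from the inverse coefficient matrix and two-sided Wald
#' p-values.
#'
#' @param data Tibble with columns `Y`, `A`, `B`, `parent_id`, and
#'   (optionally) factors `T1`, `T2` with levels cold/normal/hot. Rows
#'   with missing model variables are dropped.
#' @param grm A `recomb_grm` from [compute_grm()] covering every
#'   `parent_id`, or `NULL` for an identity relationship matrix.
#' @param use_temperature Include the temperature terms (default: yes when
#'   the columns exist and are not all missing).
#' @return An object of class `recomb_fit`; see [tidy.recomb_fit()] and
#'   [glance.recomb_fit()].
#' @export
fit_mixed_model <- function(data, grm = NULL, use_temperature = NULL) {
  has_temp <- all(c("T1", "T2") %in% names(data)) &&
    !all(is.na(data$T1)) && !all(is.na(data$T2))
  if (is.null(use_temperature)) use_temperature <- has_temp
  vars <- c("Y", "A", "B", "parent_id",
            if (use_temperature) c("T1", "T2"))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[complete.cases(data[vars]), vars]
  if (nrow(d) < 30) {
    stop("fit_mixed_model needs at least 30 complete rows", call. = FALSE)
  }

  mA <- mean(d$A)
  mB <- mean(d$B)
  X <- cbind(`(Intercept)` = 1, Ac = d$A - mA, Ac2 = (d$A - mA)^2,
             Bc = d$B - mB, Bc2 = (d$B - mB)^2)
  terms_raw <- c("(Intercept)", "A", "A2", "B", "B2")
  if (use_temperature) {
    for (v in c("T1", "T2")) {
      f <- factor(d[[v]], levels = c("cold", "normal", "hot"))
      for (lev in c("cold", "hot")) {
        if (any(f == lev)) {
          X <- cbind(X, as.numeric(f == lev))
          colnames(X)[ncol(X)] <- paste0(v, lev)
          terms_raw <- c(terms_raw, paste0(v, lev))
        }
      }
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  parents <- unique(d$parent_id)
  if (is.null(grm)) {
    G <- diag(length(parents))
    rownames(G) <- colnames(G) <- parents
  } else {
    stopifnot(inherits(grm, "recomb_grm"))
    missing_p <- setdiff(parents, grm$ids)
    if (length(missing_p)) {
      stop("GRM does not cover parent(s): ",
           paste(head(missing_p, 5), collapse = ", "), call. = FALSE)
    }
    G <- grm$G[parents, parents]
  }
  parent_idx <- match(d$parent_id, parents)

  fit <- reml_fit(d$Y, X, parent_idx, G)

  # map centered-basis estimates back to the raw scale
  S <- diag(ncol(X))
  dimnames(S) <- list(terms_raw, colnames(X))
  S["(Intercept)", c("Ac", "Ac2", "Bc", "Bc2")] <- c(-mA, mA^2, -mB, mB^2)
  S["A", "Ac2"] <- -2 * mA
  S["B", "Bc2"] <- -2 * mB
  beta <- drop(S %*% fit$beta)
  cov_beta <- S %*% fit$cov_beta %*% t(S)
  se <- sqrt(diag(cov_beta))
  z <- beta / se
  coefs <- tibble::tibble(
    term = terms_raw, estimate = unname(beta), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )

  h2 <- heritability_from_vc(fit$sigma2_g, fit$sigma2_e, fit$vc_cov)
  structure(list(
    coefficients = coefs, sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
    vc_cov = fit$vc_cov, h2 = h2$h2, h2_se = h2$se, logLik = fit$logLik,
    converged = fit$converged, boundary = fit$boundary,
    n = nrow(d), n_parents = length(parents),
    use_temperature = use_temperature,
    centering = c(A = mA, B = mB)
  ), class = "recomb_fit")
}

heritability_from_vc <- function(sigma2_g, sigma2_e, vc_cov = NULL) {
  tot <- sigma2_g + sigma2_e
  if (tot <= 0) stop("both variance components are zero; h2 undefined",
                     call. = FALSE)
  h2 <- sigma2_g / tot
  se <- NA_real_
  if (!is.null(vc_cov) && all(is.finite(vc_cov))) {
    grad <- c(sigma2_e, -sigma2_g) / tot^2
    se <- sqrt(drop(t(grad) %*% vc_cov %*% grad))
  }
  list(h2 = h2, se = se)
}

#' Heritability from variance components
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`, with a delta-method standard
#' error when the sampling covariance of the components is available.
#'
#' @param fit A `recomb_fit`, or a numeric `sigma2_g`.
#' @param sigma2_e Residual variance (when `fit` is numeric).
#' @param vc_cov Optional 2x2 sampling covariance of
#'   `(sigma2_g, sigma2_e)`.
#' @return List `h2`, `se`.
#' @export
#' @examples
#' estimate_heritability(1, 9)$h2 # 0.10
estimate_heritability <- function(fit, sigma2_e = NULL, vc_cov = NULL) {
  if (inherits(fit, "recomb_fit")) {
    if (!fit$converged) stop("fit did not converge; h2 not reported",
                             call. = FALSE)
    return(heritability_from_vc(fit$sigma2_g, fit$sigma2_e, fit$vc_cov))
  }
  heritability_from_vc(fit, sigma2_e, vc_cov)
}

#' Tidy a recombination-rate model fit
#'
#' @param x A `recomb_fit`.
#' @param ... Unused.
#' @return A tibble of fixed-effect terms with estimates, standard errors,
#'   Wald statistics, and two-sided p-values.
#' @method tidy recomb_fit
#' @export
tidy.recomb_fit <- function(x, ...) x$coefficients

#' One-row summary of a recombination-rate model fit
#'
#' @param x A `recomb_fit`.
#' @param ... Unused.
#' @return A tibble with variance components, heritability and its
#'   standard error, restricted log-likelihood, convergence flag, and
#'   sample sizes.
#' @method glance recomb_fit
#' @export
glance.recomb_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, h2 = x$h2,
    h2_se = x$h2_se, logLik = x$logLik, converged = x$converged,
    n = x$n, n_parents = x$n_parents
  )
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat("<recomb_fit> REML animal model\n")
  cat(sprintf("  n = %d meioses from %d parents; %s\n", x$n, x$n_parents,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  sigma2_g = %.3f, sigma2_e = %.3f, h2 = %.3f (SE %.3f)\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$h2_se))
  print(x$coefficients)
  invisible(x)
}
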