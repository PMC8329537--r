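# Exact REML for the single-GRM animal model
#
#   y = X beta + Z g + e,   g ~ N(0, sg2 * G),   e ~ N(0, se2 * I)
#
# Z is the meiosis -> parent incidence matrix. All likelihood evaluations
# are reduced, once per dataset, to the spectrum of Z G Z': with
# G = U D U' and W = Z U D^{1/2}, the nonzero eigenvalues t_i of W'W are
# those of ZGZ', and in the rotated basis V is diagonal. The restricted
# likelihood is then profiled: for a fixed ratio gamma = sg2/se2 the REML
# residual variance has the closed form se2(gamma) = y'P1 y / (n - f), and
# the profile is maximized over log(gamma) by Brent's method, which cannot
# diverge and returns the exact optimum of a unimodal profile. Variance
# sampling covariance comes from the numerically differentiated Hessian of
# the (unprofiled) restricted log-likelihood at the optimum.

# Precompute the spectral decomposition pieces shared by all evaluations.
reml_precompute <- function(y, X, parent_idx, G) {
  n <- length(y)
  f <- ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  W <- U[parent_idx, , drop = FALSE] %*% diag(sqrt(d), length(d))
  C <- crossprod(W)
  ec <- eigen(C, symmetric = TRUE)
  keep2 <- ec$values > max(ec$values) * 1e-12
  tval <- ec$values[keep2]
  Ut <- W %*% (ec$vectors[, keep2, drop = FALSE] %*%
                 diag(1 / sqrt(tval), length(tval)))
  list(n = n, f = f, t = tval, k = length(tval),
       yty = sum(y^2), Xty = crossprod(X, y), XtX = crossprod(X),
       yt = crossprod(Ut, y), Xt = crossprod(Ut, X))
}

# Restricted log-likelihood (up to an additive constant) at (sg2, se2),
# plus GLS pieces. With V1 = I + gamma*ZGZ' rotated to the eigenbasis,
# V^-1 = se2^-1 (I - Ut diag(1 - 1/(1 + gamma t)) Ut').
reml_eval <- function(pre, sg2, se2) {
  if (se2 <= 0 || sg2 < 0) return(list(ll = -Inf))
  gamma <- sg2 / se2
  den <- 1 + gamma * pre$t            # eigenvalues of V1 in rotated basis
  w <- (1 - 1 / den)                  # deflation weights
  yVy <- (pre$yty - sum(w * pre$yt^2)) / se2
  XVy <- (pre$Xty - crossprod(pre$Xt, w * pre$yt)) / se2
  XVX <- (pre$XtX - crossprod(pre$Xt, pre$Xt * w)) / se2
  R <- chol(XVX)
  beta <- backsolve(R, forwardsolve(t(R), XVy))
  yPy <- yVy - sum(XVy * beta)
  logdetV <- pre$n * log(se2) + sum(log(den))
  logdetXVX <- 2 * sum(log(diag(R)))
  list(ll = -0.5 * (logdetV + logdetXVX + yPy),
       beta = drop(beta), cov_beta = chol2inv(R), yPy = yPy)
}

# Profile restricted log-likelihood over gamma with closed-form se2.
reml_profile <- function(pre, gamma) {
  den <- 1 + gamma * pre$t
  w <- (1 - 1 / den)
  yVy <- pre$yty - sum(w * pre$yt^2)
  XVy <- pre$Xty - crossprod(pre$Xt, w * pre$yt)
  XVX <- pre$XtX - crossprod(pre$Xt, pre$Xt * w)
  R <- chol(XVX)
  beta <- backsolve(R, forwardsolve(t(R), XVy))
  yPy <- drop(yVy - sum(XVy * beta))
  nf <- pre$n - pre$f
  se2 <- yPy / nf
  ll <- -0.5 * (nf * log(se2) + sum(log(den)) + 2 * sum(log(diag(R))) + nf)
  list(ll = ll, se2 = se2)
}

#' Fit the GRM animal model by exact REML
#'
#' Low-level fitting routine working on a prepared design; most users call
#' [fit_mixed_model()]. See the package vignette for the algorithm.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (full column rank).
#' @param parent_idx Integer vector mapping each row of `y` to a row of
#'   `G` (multiple rows may share a parent).
#' @param G Genomic relationship matrix.
#' @param interval Search interval for `log(gamma)`, `gamma = sg2/se2`.
#' @param tol Brent tolerance on `log(gamma)`.
#' @return List with `sigma2_g`, `sigma2_e`, `beta`, `cov_beta`,
#'   `vc_cov` (2x2 sampling covariance of the variance components, `NA`
#'   at the boundary), `logLik`, `converged`, `boundary`.
#' @export
reml_fit <- function(y, X, parent_idx, G, interval = c(-14, 14),
                     tol = 1e-9) {
  pre <- reml_precompute(y, X, parent_idx, G)
  obj <- function(lg) reml_profile(pre, exp(lg))$ll
  opt <- optimize(obj, interval = interval, maximum = TRUE, tol = tol)
  # compare against the no-genetic-variance boundary
  p0 <- reml_profile(pre, 0)
  boundary <- p0$ll >= opt$objective - 1e-8
  if (boundary) {
    gamma <- 0
    se2 <- p0$se2
  } else {
    gamma <- exp(opt$maximum)
    se2 <- reml_profile(pre, gamma)$se2
  }
  sg2 <- gamma * se2
  ev <- reml_eval(pre, sg2, se2)

  vc_cov <- matrix(NA_real_, 2, 2)
  if (!boundary) {
    h <- try(optimHess(c(sg2, se2),
                       function(p) -reml_eval(pre, p[1], p[2])$ll,
                       control = list(ndeps = pmax(c(sg2, se2) * 1e-4, 1e-8))),
             silent = TRUE)
    if (!inherits(h, "try-error")) {
      vc <- try(solve(h), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0)) vc_cov <- vc
    }
  }
  hit_edge <- !boundary &&
    (abs(opt$maximum - interval[1]) < 1e-3 ||
       abs(opt$maximum - interval[2]) < 1e-3)
  list(sigma2_g = sg2, sigma2_e = se2, beta = ev$beta,
       cov_beta = ev$cov_beta, vc_cov = vc_cov, logLik = ev$ll,
       converged = !hit_edge, boundary = boundary, n = pre$n, f = pre$f)
}

#' Restricted log-likelihood of a fitted model's data at given variances
#'
#' Exposes the exact restricted log-likelihood surface (up to an additive
#' constant) for diagnostic grid checks.
#'
#' @inheritParams reml_fit
#' @param sigma2_g,sigma2_e Variance components at which to evaluate.
#' @return The restricted log-likelihood value.
#' @export
reml_loglik <- function(y, X, parent_idx, G, sigma2_g, sigma2_e) {
  pre <- reml_precompute(y, X, parent_idx, G)
  reml_eval(pre, sigma2_g, sigma2_e)$ll
}
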