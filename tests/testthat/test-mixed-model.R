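sim_fit_data <- function(n = 120, seed = 1, sg2 = 0, with_temp = TRUE) {
  set.seed(seed)
  d <- tibble::tibble(
    A = round(runif(n, 21, 90)),
    B = sample(2000:2010, n, TRUE),
    parent_id = sprintf("p%03d", rep(seq_len(n / 2), each = 2))
  )
  if (with_temp) {
    d$T1 <- factor(sample(c("cold", "normal", "hot"), n, TRUE),
                   levels = c("cold", "normal", "hot"))
    d$T2 <- factor(sample(c("cold", "normal", "hot"), n, TRUE),
                   levels = c("cold", "normal", "hot"))
  }
  g <- rnorm(n / 2, 0, sqrt(sg2))
  d$Y <- 0.5 - 0.03 * d$A + g[rep(seq_len(n / 2), each = 2)] + rnorm(n, 0, 2)
  d
}

test_that("with no genetic variance the fit collapses to OLS", {
  d <- sim_fit_data(n = 200, seed = 2, sg2 = 0, with_temp = FALSE)
  d$parent_id <- sprintf("q%03d", seq_len(nrow(d))) # one record per parent
  f <- fit_mixed_model(d, grm = NULL, use_temperature = FALSE)
  ols <- lm(Y ~ A + I(A^2) + B + I(B^2), data = d)
  expect_true(f$boundary)
  expect_equal(tidy(f)$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(tidy(f)$term, c("(Intercept)", "A", "A2", "B", "B2"))
})

test_that("the REML optimum dominates a variance-component grid", {
  d <- sim_fit_data(n = 50, seed = 3, sg2 = 2)
  X <- cbind(1, d$A - mean(d$A), (d$A - mean(d$A))^2)
  parents <- unique(d$parent_id)
  G <- diag(length(parents))
  idx <- match(d$parent_id, parents)
  fit <- reml_fit(d$Y, X, idx, G)
  grid <- expand.grid(sg2 = seq(0.01, 8, length.out = 50),
                      se2 = seq(0.5, 10, length.out = 50))
  ll <- mapply(function(a, b) reml_loglik(d$Y, X, idx, G, a, b),
               grid$sg2, grid$se2)
  expect_gte(fit$logLik, max(ll))
})

test_that("REML estimates are invariant to row order and to shifting Y", {
  d <- sim_fit_data(n = 150, seed = 4, sg2 = 3)
  f1 <- fit_mixed_model(d, grm = NULL)
  f2 <- fit_mixed_model(d[sample(nrow(d)), ], grm = NULL)
  expect_equal(glance(f1)$sigma2_g, glance(f2)$sigma2_g, tolerance = 1e-6)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
  d3 <- dplyr::mutate(d, Y = Y + 100)
  f3 <- fit_mixed_model(d3, grm = NULL)
  expect_equal(tidy(f3)$estimate[1], tidy(f1)$estimate[1] + 100,
               tolerance = 1e-5)
  expect_equal(tidy(f3)$estimate[-1], tidy(f1)$estimate[-1],
               tolerance = 1e-5)
  expect_equal(glance(f3)$h2, glance(f1)$h2, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  d <- sim_fit_data(n = 60, seed = 5, with_temp = FALSE)
  d$B <- 2005 # constant year: B2 aliased with B
  expect_error(fit_mixed_model(d, use_temperature = FALSE),
               "rank deficient.*Bc2")
})

test_that("temperature terms appear only when categories are observed", {
  d <- sim_fit_data(n = 120, seed = 6)
  d$T2[] <- "normal"
  f <- fit_mixed_model(d, grm = NULL)
  expect_true(all(c("T1cold", "T1hot") %in% tidy(f)$term))
  expect_false(any(c("T2cold", "T2hot") %in% tidy(f)$term))
})

test_that("heritability is the variance ratio with a delta-method SE", {
  expect_equal(estimate_heritability(1, 9)$h2, 0.10)
  expect_equal(estimate_heritability(0, 5)$h2, 0)
  expect_error(estimate_heritability(0, 0), "undefined")
  vc <- diag(c(0.04, 0.09))
  h <- estimate_heritability(2, 8, vc)
  grad <- c(8, -2) / 100
  expect_equal(h$se, sqrt(sum(grad^2 * c(0.04, 0.09))))
  # h2 always within [0, 1] under nonnegative components
  expect_true(h$h2 >= 0 && h$h2 <= 1)
})

test_that("a GRM shared across repeated meioses recovers genetic variance", {
  cfg <- sim_config(seed = 42)
  ph <- simulate_meiosis_phenotypes(cfg, n_dams = 300, meioses_per_dam = 4,
                                    n_markers = 400)
  ph <- adjust_rate(ph)
  grm <- compute_grm(attr(ph, "dosages"))
  f <- fit_mixed_model(dplyr::rename(ph, parent_id = dam_id), grm)
  truth <- attr(ph, "truth")
  expect_true(f$converged)
  # single replicate: loose sanity band around the generating value
  expect_lt(abs(f$sigma2_g - truth$sigma2_g), 8)
  expect_gt(f$h2, 0)
  expect_lt(f$h2, 0.35)
  expect_true(is.finite(f$h2_se) && f$h2_se > 0)
})
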