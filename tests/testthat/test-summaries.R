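test_that("spline recovers the minimum of a quadratic age trend", {
  set.seed(30)
  A <- round(runif(4000, 20, 130))
  Y <- 0.004 * (A - 65)^2 + rnorm(length(A), 0, 3)
  sp <- fit_age_spline(Y, A)
  expect_lt(abs(sp$argmin_age - 65), 10)
})

test_that("constant response gives a flat curve; linear stays monotone", {
  A <- rep(20:80, each = 2)
  sp_flat <- fit_age_spline(rep(1.5, length(A)) , A)
  expect_lt(diff(range(sp_flat$grid$fitted)), 1e-6)
  sp_lin <- fit_age_spline(0.1 * A, A)
  expect_true(all(diff(sp_lin$grid$fitted) > 0))
  expect_error(fit_age_spline(rnorm(20), rep(50, 20)), "constant")
  expect_error(fit_age_spline(rnorm(9), seq(20, 28)), "10 distinct")
})

test_that("group summaries report n, mean, and sd/sqrt(n)", {
  g <- group_summary(c(2, 4), c("g1", "g1"))
  expect_equal(g$mean, 3)
  expect_equal(g$se, 1)
  one <- group_summary(c(1, 2, 3), rep("all", 3))
  expect_equal(one$mean, 2)
  expect_equal(one$se, sd(c(1, 2, 3)) / sqrt(3))
  # empty factor level reported with n = 0 and undefined mean
  empty <- group_summary(c(1, 2), factor(c("a", "a"), levels = c("a", "b")))
  expect_equal(empty$n[empty$group == "b"], 0)
  expect_true(is.na(empty$mean[empty$group == "b"]))
})

test_that("group summaries match a streaming oracle on a 10-group table", {
  set.seed(31)
  y <- rnorm(500)
  grp <- sample(1:10, 500, TRUE)
  out <- group_summary(y, grp)
  for (g in 1:10) {
    # independent accumulation loop
    n <- 0; s <- 0; s2 <- 0
    for (i in which(grp == g)) { n <- n + 1; s <- s + y[i]; s2 <- s2 + y[i]^2 }
    expect_equal(out$n[out$group == g], n)
    expect_equal(out$mean[out$group == g], s / n)
    expect_equal(out$se[out$group == g],
                 sqrt((s2 - s^2 / n) / (n - 1)) / sqrt(n))
  }
})

test_that("temperature boxplot statistics follow the 1.5 IQR rule", {
  set.seed(32)
  y <- c(rnorm(200, 1), rnorm(200, 0), rnorm(200, -1))
  cat3 <- rep(c("hot", "normal", "cold"), each = 200)
  out <- temp_group_summary(y, cat3)
  expect_equal(out$category, c("cold", "normal", "hot"))
  hot <- y[cat3 == "hot"]
  bs <- grDevices::boxplot.stats(hot)$stats
  row <- out[out$category == "hot", ]
  expect_equal(row$median, bs[3])
  expect_equal(c(row$whisker_low, row$q1, row$q3, row$whisker_high),
               bs[c(1, 2, 4, 5)])
  # identical values in a category -> zero IQR; absent categories warn
  z <- expect_warning(temp_group_summary(rep(2, 5), rep("normal", 5)),
                      "absent")
  expect_equal(z$q1, z$q3)
})

test_that("generative temperature effects order the group means", {
  cfg <- sim_config(seed = 50)
  set.seed(51)
  n <- 20000
  cat3 <- factor(rep(c("cold", "normal", "hot"), length.out = n),
                 levels = c("cold", "normal", "hot"))
  shift <- c(cold = cfg$beta_cold, normal = 0, hot = cfg$beta_hot)
  lam <- 23.2 + shift[as.character(cat3)] + rnorm(n, 0, sqrt(75))
  y <- draw_crossover_count(lam)
  y <- y - mean(y)
  out <- temp_group_summary(y, cat3)
  m <- stats::setNames(out$mean, out$category)
  expect_gt(m[["hot"]], m[["normal"]])
  expect_gt(m[["normal"]], m[["cold"]])
})
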