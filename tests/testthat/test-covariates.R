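test_that("maternal age counts complete calendar months", {
  expect_equal(maternal_age_months("2010-01-01", "2014-06-01"), 53L)
  expect_equal(maternal_age_months("2010-01-01", "2010-01-01"), 0L)
  expect_equal(maternal_age_months("2010-01-01", "2010-03-01"), 2L)
  expect_equal(maternal_age_months("2010-01-15", "2010-03-14"), 1L)
  expect_error(maternal_age_months("2014-06-01", "2010-01-01"), "before")
})

test_that("month-prior temperature lookup handles year rollover and gaps", {
  s <- tibble::tibble(farm_id = "F1", year = c(2015, 2014), month = c(5, 12),
                      tavg_c = c(20, -3))
  expect_equal(temp_month_prior(s, as.Date("2015-06-15"), "F1"), 20)
  expect_equal(temp_month_prior(s, as.Date("2015-01-10"), "F1"), -3)
  expect_true(is.na(temp_month_prior(s, as.Date("2015-09-01"), "F1")))
  expect_true(is.na(temp_month_prior(s, as.Date("2015-06-15"), "F9")))
})

test_that("temperature categories use strict hot/cold thresholds", {
  expect_equal(as.character(categorize_temperature(c(30, 0, 26.67, 4.44, 15))),
               c("hot", "cold", "normal", "normal", "normal"))
  expect_equal(as.character(categorize_temperature(26.68)), "hot")
  expect_equal(as.character(categorize_temperature(4.43)), "cold")
  expect_error(categorize_temperature(Inf), "finite")
  # partition: exactly one category per finite value, monotone in t
  t <- seq(-20, 40, by = 0.5)
  cats <- categorize_temperature(t)
  expect_false(anyNA(cats))
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("age groups bin from 20 months in 10-month increments", {
  expect_equal(age_group(c(23, 65, 127)), c(1L, 5L, 10L))
  expect_equal(age_group(c(20, 29.9, 30, 119, 120)), c(1L, 1L, 2L, 10L, 10L))
  expect_true(is.na(age_group(19)))
  # bins cover [20, Inf) without overlap
  a <- seq(20, 200, by = 0.25)
  g <- age_group(a)
  expect_false(anyNA(g))
  expect_true(all(diff(g) >= 0))
  expect_equal(sort(unique(g)), 1:10)
})

test_that("rate adjustment reproduces hand-computed least-squares residuals", {
  rec <- tibble::tibble(
    R = c(20, 25, 23, 30, 18),
    chip_class = c("a", "a", "b", "b", "a"),
    informative_n = c(100, 120, 90, 140, 110)
  )
  X <- cbind(1, rec$chip_class == "b", rec$informative_n)
  beta <- solve(t(X) %*% X, t(X) %*% rec$R)
  expect_equal(adjust_rate(rec)$Y, drop(rec$R - X %*% beta),
               ignore_attr = TRUE, tolerance = 1e-10)
  # residuals orthogonal to every design column
  out <- adjust_rate(rec)
  expect_lt(abs(sum(out$Y * rec$informative_n)), 1e-8)
  expect_lt(abs(sum(out$Y[rec$chip_class == "a"])), 1e-8)
  expect_lt(abs(sum(out$Y[rec$chip_class == "b"])), 1e-8)
})

test_that("constant covariates reduce the adjustment to centering", {
  rec <- tibble::tibble(R = c(10, 20, 33), chip_class = "a",
                        informative_n = 100)
  expect_equal(adjust_rate(rec)$Y, rec$R - mean(rec$R))
  expect_error(adjust_rate(rec[1, ]), "at least 2")
  # shifting all counts by a constant leaves residuals unchanged
  rec2 <- dplyr::mutate(rec, R = R + 7)
  expect_equal(adjust_rate(rec2)$Y, adjust_rate(rec)$Y)
})

test_that("covariate table carries ages, birth years, and categories", {
  b <- small_clean_bundle()
  fam <- extract_three_gen_families(b$pedigree, colnames(b$genotypes))
  rec <- tibble::tibble(dam_id = fam$dam_id, offspring_id = fam$offspring_id)
  cov <- build_covariates(rec, b$pedigree, b$temperature)
  expect_equal(nrow(cov), nrow(rec))
  expect_true(all(cov$A > 0))
  ped_years <- lubridate::year(
    b$pedigree$birth_date[match(cov$dam_id, b$pedigree$animal_id)])
  expect_equal(cov$B, ped_years)
  expect_true(all(cov$temp_complete))
  expect_true(all(levels(cov$T1) == c("cold", "normal", "hot")))
})
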