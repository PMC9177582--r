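test_that("MAPE matches direct evaluation and its invariances", {
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  expect_equal(mape(c(3, 7, 11), c(3, 7, 11)), 0)
  # scaling both series leaves MAPE unchanged
  expect_equal(mape(5 * c(100, 200), 5 * c(110, 180)), 10)
  # zero-model points are skipped with a warning, M reduced
  expect_warning(m <- mape(c(0, 100), c(5, 110)), "skipped")
  expect_equal(m, 10)
  expect_warning(m0 <- mape(c(0, 0), c(1, 2)))
  expect_true(is.na(m0))
})

test_that("cumulative counts behave at the boundaries in both modes", {
  coh <- generate_cohort(sim_config(500, theta_true = fast_theta(),
                                    seed = 31))
  ages <- coh$tumor_age_years
  # data mode
  expect_equal(cumulative_counts(coh, "bone", min(ages) - 0.1), 0)
  expect_equal(cumulative_counts(coh, "bone", max(ages) + 0.1),
               sum(coh$bone))
  x <- cumulative_counts(coh, "lung", seq(0, 8, by = 0.5))
  expect_true(all(diff(x) >= 0))
  # model mode: zero rates predict zero counts; expected counts are
  # monotone and bounded by the group size
  expect_equal(cumulative_counts(coh, "bone", c(1, 5),
                                 theta = rate_vector()), c(0, 0))
  xm <- cumulative_counts(coh, "bone", seq(0, 8, by = 0.5),
                          theta = fast_theta())
  expect_true(all(diff(xm) >= 0))
  expect_true(all(xm <= nrow(coh)))
  expect_warning(cumulative_counts(coh[0, ], "bone", 1), "empty")
})

test_that("model and data cumulative curves agree on a well-specified cohort", {
  th <- fast_theta()
  coh <- generate_cohort(sim_config(2e4, theta_true = th, seed = 32))
  t_grid <- seq(1, 6, by = 1)
  for (s in c("bone", "lung")) {
    xm <- cumulative_counts(coh, s, t_grid, theta = th)
    xd <- cumulative_counts(coh, s, t_grid)
    # binomial-scale agreement at each point
    expect_true(all(abs(xd - xm) <= 4 * sqrt(pmax(xm, 1))))
  }
})

test_that("MAPE of the generating model decreases with cohort size", {
  th <- fast_theta()
  err <- vapply(c(500, 5000, 5e4), function(n) {
    coh <- generate_cohort(sim_config(n, theta_true = th, seed = 33))
    t_grid <- seq(0.5, 6, by = 0.5)
    xm <- cumulative_counts(coh, "bone", t_grid, theta = th)
    xd <- cumulative_counts(coh, "bone", t_grid)
    suppressWarnings(mape(xm, xd))
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("cross-validation is reproducible and rejects undersized folds", {
  coh <- generate_cohort(sim_config(1200, theta_true = fast_theta(),
                                    seed = 34))
  cv1 <- cross_validate(coh, k = 4, seed = 8, n_starts = 1, max_eval = 800)
  cv2 <- cross_validate(coh, k = 4, seed = 8, n_starts = 1, max_eval = 800)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$mape, cv2$mape)
  expect_equal(dim(cv1$theta), c(4L, 6L))
  expect_equal(dim(cv1$mape), c(4L, 4L))
  expect_true(all(cv1$mape >= 0, na.rm = TRUE))
  expect_true(all(table(cv1$fold) == 300))
  expect_error(cross_validate(coh[1:20, ], k = 20), "too small")
})

test_that("metastasis probabilities have the state-1 closed form", {
  th <- fast_theta()
  pr <- metastasis_probability(th, t = c(0, 1, 3, 8))
  expect_equal(pr$p_any[1], 0)
  lambda <- sum(as.numeric(th)[1:4])
  expect_equal(pr$p_any, 1 - exp(-lambda * pr$time_years), tolerance = 1e-9)
  expect_true(all(diff(pr$p_any) > 0))
  rows <- as.matrix(pr[, paste0("P", 1:16)])
  expect_equal(rowSums(rows), rep(1, 4), tolerance = 1e-9)
  # diameter interface: 5 mm enters at its imputed 2.4-year age, and the
  # 10-year-ahead risk evaluates at age + 10
  pd <- metastasis_probability(th, diameter_mm = 5)
  expect_equal(round(pd$time_years, 1), 2.4)
  p10 <- metastasis_probability(th, t = pd$time_years + 10)
  expect_equal(p10$p_any,
               1 - exp(-lambda * (pd$time_years + 10)), tolerance = 1e-9)
  expect_error(metastasis_probability(th), "exactly one")
  expect_error(metastasis_probability(th, t = 1, diameter_mm = 5),
               "exactly one")
})

test_that("derived ratios implement the blood-flow normalization", {
  th <- rate_vector(tubo = 0.006, tulu = 0.00269, tuli = 0.0015,
                    tubr = 0.0004, luli = 0.126, lubr = 0.0404)
  r <- derived_ratios(th)
  expect_equal(r$secondary_primary_liver, 0.126 / 0.0015)
  expect_equal(r$secondary_primary_brain, 0.0404 / 0.0004)
  expect_equal(r$colonizing_ability, (0.126 / 0.065) / (0.0404 / 0.12),
               tolerance = 1e-9)
  expect_equal(round(r$colonizing_ability, 2), 5.76)
  # lung influx is far below its outflux under these rates
  expect_lt(r$lung_influx, 0.05 * r$lung_outflux)
  # equal rates give a unit secondary/primary ratio
  expect_equal(derived_ratios(rate_vector(tuli = 0.2, luli = 0.2,
                                          tubr = 1, lubr = 1))$secondary_primary_liver,
               1)
  expect_warning(derived_ratios(rate_vector(luli = 1, lubr = 1, tubr = 1)),
                 "luli/tuli undefined")
  r0 <- suppressWarnings(derived_ratios(rate_vector(luli = 1)))
  expect_true(is.na(r0$secondary_primary_liver))
  expect_true(is.na(r0$secondary_primary_brain))
})
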