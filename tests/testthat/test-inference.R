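test_that("likelihood of a metastasis-free patient has the closed form", {
  th <- rate_vector(tubo = 0.05, tulu = 0.03, tuli = 0.02, tubr = 0.01)
  coh <- generate_cohort(sim_config(1, theta_true = rate_vector(), seed = 3))
  coh$state_index <- 1L
  t <- coh$tumor_age_years
  expect_equal(negative_log_likelihood(coh, th),
               (0.05 + 0.03 + 0.02 + 0.01) * t, tolerance = 1e-3)
  # empty product
  expect_equal(negative_log_likelihood(coh[0, ], th), 0)
})

test_that("grouping by multiplicity and patient order do not change the NLL", {
  coh <- generate_cohort(sim_config(400, theta_true = fast_theta(),
                                    seed = 21))
  th <- fast_theta()
  nll <- negative_log_likelihood(coh, th)
  # duplicate every patient: NLL doubles exactly
  expect_equal(negative_log_likelihood(rbind(coh, coh), th), 2 * nll)
  # permutation invariance
  perm <- coh[sample(nrow(coh)), ]
  expect_equal(negative_log_likelihood(perm, th), nll)
  # solver choice changes the value only at the Euler error scale
  expect_equal(negative_log_likelihood(coh, th, method = "expm"), nll,
               tolerance = 1e-4)
})

test_that("the likelihood peaks near the generating rates", {
  coh <- generate_cohort(sim_config(2e4, theta_true = fast_theta(),
                                    seed = 22))
  th <- fast_theta()
  nll_true <- negative_log_likelihood(coh, th)
  expect_lt(nll_true, negative_log_likelihood(coh, as_rate_vector(2 * th)))
  expect_lt(nll_true,
            negative_log_likelihood(coh, as_rate_vector(0.5 * th)))
})

test_that("MLE recovers rates on a simulated cohort and is seed-stable", {
  th <- fast_theta()
  coh <- generate_cohort(sim_config(5000, theta_true = th, seed = 23))
  fit <- fit_mle(coh, n_starts = 1)
  expect_true(fit$converged)
  rel <- abs(as.numeric(fit$theta_hat) - as.numeric(th)) / as.numeric(th)
  expect_true(all(rel < 0.35))
  # a different multi-start seed lands on the same optimum
  fit2 <- fit_mle(coh, n_starts = 2, seed = 99)
  expect_equal(as.numeric(fit2$theta_hat), as.numeric(fit$theta_hat),
               tolerance = 0.05)
})

test_that("a cohort with no metastases drives all rates to the lower bound", {
  coh <- generate_cohort(sim_config(200, theta_true = rate_vector(),
                                    seed = 4))
  fit <- fit_mle(coh, n_starts = 1, max_eval = 1500)
  # the secondary rates never enter the likelihood of a lung-free cohort,
  # so only the four primary rates are identified (and pushed to zero)
  expect_true(all(as.numeric(fit$theta_hat)[1:4] < 1e-3))
  expect_lt(fit$nll, negative_log_likelihood(coh, rate_vector(tubo = 0.01)))
})

test_that("fit input validation catches bad bounds and unprepared cohorts", {
  coh <- generate_cohort(sim_config(50, seed = 6))
  expect_error(fit_mle(coh, lower = 1, upper = 1), "bounds")
  expect_error(fit_mle(coh, init = 100), "init")
  bad <- coh
  bad$tumor_age_years <- NULL
  expect_error(negative_log_likelihood(bad, rate_vector()), "prepare")
})

test_that("parametric bootstrap is reproducible and reports diagnostics", {
  th <- fast_theta()
  coh <- generate_cohort(sim_config(1500, theta_true = th, seed = 25))
  fit <- fit_mle(coh, n_starts = 1, max_eval = 1500)
  b1 <- bootstrap_ci(fit, coh, B = 3, seed = 11, max_eval = 800)
  b2 <- bootstrap_ci(fit, coh, B = 3, seed = 11, max_eval = 800)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$ci_upper, b2$ci_upper)
  expect_equal(nrow(b1$bootstrap_samples), b1$B_effective)
  expect_true(all(b1$ci_lower <= b1$ci_upper))
  expect_warning(bootstrap_ci(fit, coh, B = 1, max_eval = 400),
                 "degenerate")
  # report serializes with CIs
  path <- tempfile(fileext = ".json")
  write_fit_report(b1, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$theta_hat$tubo, fit$theta_hat[["tubo"]])
  expect_length(rep$ci_lower, 6L)
  unlink(path)
  # CI plot renders without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(b1))
})
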