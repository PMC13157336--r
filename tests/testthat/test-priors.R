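test_that("beta_mean matches the published placebo mean and obvious symmetries", {
  expect_equal(round(beta_mean(placebo_fixture()), 2), 0.22)
  expect_equal(beta_mean(beta_prior(1, 1)), 0.5)
  expect_equal(beta_mean(beta_prior(5, 5)), 0.5)
})

test_that("beta_quantile reproduces the placebo 90% interval and is a proper inverse CDF", {
  p0 <- placebo_fixture()
  expect_equal(round(beta_quantile(p0, 0.05), 2), 0.05)
  expect_equal(round(beta_quantile(p0, 0.95), 2), 0.46)
  expect_equal(beta_quantile(beta_prior(1, 1), 0.25), 0.25)

  qs <- seq(0.01, 0.99, by = 0.01)
  for (pr in list(p0, beta_prior(0.5, 0.5), beta_prior(20, 3))) {
    vals <- beta_quantile(pr, qs)
    expect_true(all(diff(vals) > 0))
    expect_equal(pbeta(vals, pr$alpha, pr$beta), qs, tolerance = 1e-9)
  }
  expect_error(beta_quantile(p0, 0), class = "priorelicit_domain_error")
  expect_error(beta_quantile(p0, 1.2), class = "priorelicit_domain_error")
})

test_that("Beta fitting round-trips median/quantile pairs across the shape range", {
  shapes <- c(0.5, 1, 2.16, 7.57, 20, 50)
  for (a in shapes) for (b in c(0.5, 5, 50)) {
    pr <- beta_prior(a, b)
    ans <- placebo_answers(beta_quantile(pr, 0.5), beta_quantile(pr, 0.95), 0.95)
    fit <- fit_beta_from_answers(ans)
    expect_equal(fit$alpha, a, tolerance = 1e-3)
    expect_equal(fit$beta, b, tolerance = 1e-3)
  }
})

test_that("Beta fitting honours its conventions and guards", {
  # symmetry: median 0.5 with a symmetric bound pair forces alpha == beta
  fit <- fit_beta_from_answers(placebo_answers(0.5, 0.75, 0.75))
  expect_equal(fit$alpha, fit$beta, tolerance = 1e-6)
  expect_equal(beta_quantile(fit, 0.5), 0.5, tolerance = 1e-7)

  # the convention matches the median, not the mean
  fit2 <- fit_beta_from_answers(placebo_answers(0.2218, 0.46, 0.95))
  expect_equal(beta_quantile(fit2, 0.5), 0.2218, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(beta_mean(fit2), 0.2218, tolerance = 1e-4)))

  # residual tolerance is enforced: an absurdly tight bound cannot be matched
  expect_error(fit_beta_from_answers(placebo_answers(0.5, 0.5 + 1e-12, 0.999)),
               class = "priorelicit_fit_error")

  # degenerate probabilities are rejected at construction
  expect_error(placebo_answers(0, 0.4), class = "priorelicit_domain_error")
  expect_error(placebo_answers(0.2, 1), class = "priorelicit_domain_error")
  expect_error(placebo_answers(0.4, 0.2), class = "priorelicit_domain_error")
})

test_that("log-odds-ratio fitting is the closed form and round-trips exactly", {
  # construction: median OR e^1.10, 95% bound at e^(1.10 + 1.645*1.70)
  z <- qnorm(0.95)
  ans <- effect_answers(exp(1.10), exp(1.10 + z * 1.70), 0.95)
  fit <- fit_logor_from_answers(ans)
  expect_equal(fit$mean, 1.10, tolerance = 1e-12)
  expect_equal(fit$sd, 1.70, tolerance = 1e-12)

  # no expected benefit: unit odds ratio maps to mean zero
  expect_equal(fit_logor_from_answers(effect_answers(1, 3))$mean, 0)

  # exact round-trip across a parameter grid
  for (m in c(-0.5, 0, 0.62, 1.90)) for (s in c(0.3, 1.04, 2.20)) {
    for (bp in c(0.8, 0.95)) {
      zz <- qnorm(bp)
      back <- fit_logor_from_answers(effect_answers(exp(m), exp(m + zz * s), bp))
      expect_equal(back$mean, m, tolerance = 1e-12)
      expect_equal(back$sd, s, tolerance = 1e-12)
    }
  }
  expect_error(effect_answers(-1, 2), class = "priorelicit_domain_error")
  expect_error(effect_answers(3, 2), class = "priorelicit_domain_error")
})

test_that("sd intervals, point odds ratios and superiority probabilities behave", {
  upa <- logor_prior(1.10, 1.70)
  expect_equal(round(logor_sd_interval(upa, 1), 1), c(-0.6, 2.8))
  expect_equal(round(logor_sd_interval(upa, 2), 1), c(-2.3, 4.5))
  expect_equal(logor_sd_interval(upa, 0), c(1.10, 1.10))
  expect_equal(round(odds_ratio_point(upa)), 3)
  expect_equal(odds_ratio_point(logor_prior(0, 2)), 1)
  expect_equal(round(exp(4.5)), 90)

  # widths scale linearly in k, and k = 1.645 is the equal-tailed 90% interval
  w1 <- diff(logor_sd_interval(upa, 1)); w3 <- diff(logor_sd_interval(upa, 3))
  expect_equal(w3, 3 * w1)
  expect_equal(logor_sd_interval(upa, qnorm(0.95)),
               qnorm(c(0.05, 0.95), 1.10, 1.70), tolerance = 1e-12)

  expect_equal(prior_prob_superiority(logor_prior(0, 0.64)), 0.5)
  expect_equal(prior_prob_superiority(upa), pnorm(1.10 / 1.70))
  expect_equal(prior_prob_superiority(logor_prior(1.90, 2.20)), pnorm(1.90 / 2.20))
})
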