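test_that("descriptive summaries use arithmetic mean, n-1 SD and the median", {
  s <- summarize_concentrations(c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$median, 20)
  s0 <- summarize_concentrations(c(100, 100, 100))
  expect_equal(s0$sd, 0)
  expect_equal(s0$median, 100)
  expect_error(summarize_concentrations(numeric(0)), "no concentration")
  expect_error(summarize_concentrations(c(10, -1, 5)), "index 2")
  expect_error(summarize_concentrations(c(10, 0)), "index 2")
})

test_that("method-of-moments fit reproduces input moments exactly", {
  cases <- list(c(131, 90), c(85, 56), c(17, 16), c(30, 34), c(1, 0.001),
                c(1e4, 3e4))
  for (ms in cases) {
    fit <- fit_lognormal_mom(ms[1], ms[2])
    expect_equal(mean(fit), ms[1], tolerance = 1e-12)
    implied_sd <- sqrt(expm1(fit$sigma^2)) * exp(fit$mu + fit$sigma^2 / 2)
    expect_equal(implied_sd, ms[2], tolerance = 1e-12)
  }
})

test_that("fitted log-scale parameters match the closed form on survey strata", {
  fit <- fit_lognormal_mom(131, 90)
  expect_equal(fit$mu, 4.6819, tolerance = 1e-4)
  expect_equal(fit$sigma, 0.6218, tolerance = 1e-4)
  fit2 <- fit_lognormal_mom(30, 34)
  expect_equal(fit2$mu, 2.9881, tolerance = 1e-4)
  expect_equal(fit2$sigma, 0.9089, tolerance = 1e-4)
})

test_that("fit degenerates gracefully as sd shrinks to zero", {
  fit <- fit_lognormal_mom(80, 1e-9)
  expect_lt(fit$sigma, 1e-9)
  expect_equal(fit$mu, log(80), tolerance = 1e-12)
  expect_error(fit_lognormal_mom(80, 0), "positive")
  expect_error(fit_lognormal_mom(-3, 5), "positive")
})

test_that("MoM fit agrees with an independent distribution-fitting routine", {
  skip_if_not_installed("fitdistrplus")
  set.seed(11)
  x <- rlnorm(4000, meanlog = 3.2, sdlog = 0.7)
  # fitdistrplus matches raw moments with the n-denominator variance
  ours <- fit_lognormal_mom(mean(x), sqrt(mean((x - mean(x))^2)))
  ref <- fitdistrplus::fitdist(x, "lnorm", method = "mme",
                               order = 1:2, memp = function(x, order) mean(x^order))
  expect_equal(ours$mu, unname(ref$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(ours$sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-6)
})

test_that("poor median agreement triggers an adequacy warning, not an error", {
  expect_warning(fit_lognormal_mom(30, 34, median = 16), "adequacy|poorly")
  expect_silent(fit_lognormal_mom(131, 90, median = 100))
})

test_that("analytic exceedance matches the lognormal upper tail", {
  fit <- fit_lognormal_mom(131, 90)
  expect_equal(exceedance_analytic(fit, 55), 0.8610, tolerance = 1e-3)
  fit_ob <- fit_lognormal_mom(30, 34)
  expect_equal(exceedance_analytic(fit_ob, 60), 0.1118, tolerance = 1e-3)
  # limits: everything exceeds a vanishing threshold, nothing a huge one
  expect_equal(exceedance_analytic(fit, 1e-12), 1)
  expect_lt(exceedance_analytic(fit, 1e9), 1e-12)
  expect_error(exceedance_analytic(fit, 0), "positive")
})

test_that("analytic exceedance is strictly decreasing in the threshold", {
  fit <- fit_lognormal_mom(17, 16)
  th <- exp(seq(log(0.1), log(500), length.out = 60))
  fr <- exceedance_analytic(fit, th)
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("empirical exceedance counts strict exceedances only", {
  expect_equal(exceedance_empirical(c(10, 20, 30), 20), 1 / 3)
  expect_equal(exceedance_empirical(c(10, 20, 30), 5), 1)
  expect_equal(exceedance_empirical(c(10, 20, 30), 30), 0)  # tie compliant
  expect_error(exceedance_empirical(numeric(0), 5), "no concentration")
})

test_that("empirical exceedance converges to the analytic tail", {
  fit <- fit_lognormal_mom(85, 56)
  set.seed(7)
  x <- rlnorm(1e5, fit$mu, fit$sigma)
  for (th in c(30, 55, 100, 200)) {
    expect_equal(exceedance_empirical(x, th), exceedance_analytic(fit, th),
                 tolerance = 0.01)
  }
})

test_that("maximum-likelihood fit recovers parameters from raw records", {
  set.seed(5)
  x <- rlnorm(1e4, 2.5, 0.8)
  fit <- fit_lognormal_mle(x)
  expect_equal(fit$mu, 2.5, tolerance = 0.05)
  expect_equal(fit$sigma, 0.8, tolerance = 0.05)
  expect_error(fit_lognormal_mle(c(1)), "two records")
  expect_error(fit_lognormal_mle(c(1, -2)), "positive")
})
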