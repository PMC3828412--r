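test_that("point-mass time fractions give the back-calculated exposure means", {
  pm <- time_use_model(0.657, 0.176, sd_home = 0, sd_office = 0)
  d <- simulate_personal_exposure(fit_stratum("dwelling", "formaldehyde"),
                                  fit_stratum("office", "formaldehyde"),
                                  pm, n_trials = 5e4, seed = 10,
                                  compound = "formaldehyde")
  # E[e_home] = f_home * E[C_home] = 0.657 * 131 ~ 86 ug/m3
  expect_equal(mean(d$e_home), 0.657 * 131, tolerance = 0.02)
  expect_equal(mean(d$e_office), 0.176 * 85, tolerance = 0.02)
  expect_equal(d$e_total, d$e_home + d$e_office, tolerance = 1e-12)
})

test_that("zero time fractions give zero exposure", {
  z <- time_use_model(0, 0, sd_home = 0, sd_office = 0)
  d <- simulate_personal_exposure(fit_stratum("dwelling", "benzene"),
                                  fit_stratum("office", "benzene"),
                                  z, n_trials = 100, seed = 1,
                                  compound = "benzene")
  expect_true(all(d$e_total == 0))
})

test_that("degenerate concentration and time spread give the closed-form limit", {
  home <- fit_lognormal_mom(120, 1e-9)
  office <- fit_lognormal_mom(60, 1e-9)
  pm <- time_use_model(0.6, 0.2, sd_home = 0, sd_office = 0)
  d <- simulate_personal_exposure(home, office, pm, n_trials = 50, seed = 2,
                                  compound = "x")
  expect_equal(d$e_total, rep(0.6 * 120 + 0.2 * 60, 50), tolerance = 1e-6)
  s <- summary(d)
  expect_equal(s$sd[s$microenvironment == "total"], 0, tolerance = 1e-6)
  expect_equal(s$mean[s$microenvironment == "total"], 84, tolerance = 1e-6)
})

test_that("independence makes mean exposure factorize over fractions", {
  d <- simulate_personal_exposure(fit_stratum("dwelling", "benzene"),
                                  fit_stratum("office", "benzene"),
                                  time_use_model(), n_trials = 1e5, seed = 33,
                                  compound = "benzene")
  tu <- sample_time_use(time_use_model(), 1e5, seed = 34)
  expect_equal(mean(d$e_home), mean(tu$f_home) * 17, tolerance = 0.02)
  expect_equal(mean(d$e_office), mean(tu$f_office) * 30, tolerance = 0.02)
})

test_that("exposure summaries match an independent re-computation", {
  d <- simulate_personal_exposure(fit_stratum("dwelling", "formaldehyde"),
                                  fit_stratum("office", "formaldehyde"),
                                  time_use_model(), n_trials = 4000, seed = 55,
                                  compound = "formaldehyde")
  s <- summary(d)
  tot <- s[s$microenvironment == "total", ]
  # oracle: plain base-R statistics on the raw draw vector
  x <- d$e_home + d$e_office
  expect_equal(tot$mean, sum(x) / length(x), tolerance = 1e-12)
  expect_equal(tot$median, quantile(x, 0.5, type = 7, names = FALSE),
               tolerance = 1e-12)
  expect_equal(tot$p95, quantile(x, 0.95, type = 7, names = FALSE),
               tolerance = 1e-12)
  expect_equal(tot$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
})

test_that("summaries are invariant to the order of draws", {
  d <- simulate_personal_exposure(fit_stratum("dwelling", "benzene"),
                                  fit_stratum("office", "benzene"),
                                  time_use_model(), n_trials = 999, seed = 8,
                                  compound = "benzene")
  set.seed(1)
  shuffled <- d[sample(nrow(d)), ]
  attributes(shuffled) <- c(attributes(shuffled),
                            attributes(d)[c("compound", "n_trials", "seed")])
  class(shuffled) <- class(d)
  expect_equal(summary(shuffled)[-1], summary(d)[-1], tolerance = 1e-12)
})

test_that("exposure simulation is deterministic under a fixed seed", {
  args <- list(fit_stratum("dwelling", "formaldehyde"),
               fit_stratum("office", "formaldehyde"),
               time_use_model(), n_trials = 500, compound = "formaldehyde")
  a <- do.call(simulate_personal_exposure, c(args, seed = 77))
  b <- do.call(simulate_personal_exposure, c(args, seed = 77))
  expect_identical(a, b)
  expect_error(do.call(simulate_personal_exposure, args), "seed")
})
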