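FAST_GRID <- grid_config(n_m = 25, n_w = 20, n_lapse = 10, n_eta = 6)

test_that("psychometric data validates counts, ordering, and guess rate", {
  d <- psychometric_data(c(1, 2, 4), c(10, 10, 10), c(4, 6, 9), 1 / 3)
  expect_s3_class(d, "psychometric_data")
  expect_error(psychometric_data(c(2, 1, 4), rep(10, 3), rep(5, 3), 1 / 3),
               "increasing")
  expect_error(psychometric_data(c(1, 2, 4), rep(10, 3), c(4, 11, 5), 1 / 3),
               "n_correct")
  expect_error(psychometric_data(c(-1, 2, 4), rep(10, 3), rep(5, 3), 1 / 3),
               "positive")
})

test_that("with overdispersion off, the posterior matches a binomial-grid oracle", {
  obs <- observer_model(midpoint = 8, width = 1.2, lapse = 0.02, guess = 1 / 3)
  d <- simulate_psychometric_responses(obs, 2^(0:6), 40, seed = 5)
  g <- grid_config(n_m = 15, n_w = 12, n_lapse = 6, n_eta = 1, eta_max = 0)
  fit <- fit_psychometric(d, grid = g)
  oracle <- binomial_grid_posterior(fit)
  expect_equal(array(fit$posterior, dim = dim(oracle)), oracle,
               tolerance = 1e-8)
})

test_that("fits recover generating parameters from simulated observers", {
  obs <- observer_model(midpoint = 0.5, width = 1.5, lapse = 0.02,
                        guess = 1 / 3)
  d <- simulate_psychometric_responses(obs, 0.05 * 2^(0:6), 500, seed = 31)
  fit <- fit_psychometric(d, grid = grid_config(n_m = 35, n_w = 25,
                                                n_lapse = 10, n_eta = 6))
  thr <- threshold_at(fit, 0.794)
  true_thr <- observer_threshold(obs, 0.794)
  expect_lt(abs(thr$threshold - true_thr) / true_thr, 0.15)
  expect_true(thr$ci["lower"] <= thr$threshold &&
                thr$threshold <= thr$ci["upper"])
  expect_false(fit$boundary)
})

test_that("thresholds at conventional targets match closed forms", {
  # 2AFC, lapse 0: the 75% point is the sigmoid midpoint
  obs2 <- observer_model(midpoint = 30, width = 2, lapse = 0, guess = 0.5)
  expect_equal(observer_threshold(obs2, 0.75), 30, tolerance = 1e-12)
  # 3AFC, lapse 0: the 79.4% point solves S = (0.794 - 1/3) / (2/3)
  obs3 <- observer_model(midpoint = 30, width = 2, lapse = 0, guess = 1 / 3)
  f <- (0.794 - 1 / 3) / (1 - 1 / 3)
  expected <- exp(log(30) + 2 * qlogis(f) / (2 * qlogis(0.95)))
  expect_equal(observer_threshold(obs3, 0.794), expected, tolerance = 1e-12)
  # increasing the lapse shifts the target point upward, monotonically
  thr_by_lapse <- vapply(c(0, 0.02, 0.05), function(l) {
    observer_threshold(observer_model(30, 2, l, 1 / 3), 0.794)
  }, numeric(1))
  expect_true(all(diff(thr_by_lapse) > 0))
})

test_that("degenerate data are flagged, not fatal", {
  # all-chance data: the fitted curve stays flat at the guess rate over the
  # tested range and the threshold is pushed above it with wide uncertainty
  lv <- 2^(0:6)
  flat <- psychometric_data(lv, rep(60, 7), round(60 / 3 + c(1, -1, 0, 2, -2, 1, 0)),
                           1 / 3)
  fit <- fit_psychometric(flat, grid = FAST_GRID)
  e <- fit$estimate
  p_hat <- flat$guess + (1 - flat$guess - e["lapse"]) *
    plogis(2 * qlogis(0.95) * (log(lv) - e["m"]) / e["w"])
  expect_true(all(p_hat < flat$guess + 0.1))
  thr <- threshold_at(fit, 0.794)
  expect_gt(thr$ci["upper"], lv[6])
  expect_true(fit$boundary)
  # all-correct data: posterior piles at the low edge -> boundary flag
  perfect <- psychometric_data(lv, rep(20, 7), rep(20, 7), 1 / 3)
  fit2 <- fit_psychometric(perfect, grid = FAST_GRID)
  expect_true(fit2$boundary)
  expect_error(threshold_at(fit2, 0.2), "guess rate")
  expect_error(threshold_at(fit2, 0.99), "ceiling")
})

test_that("posterior credible intervals contract as trial counts double", {
  obs <- observer_model(midpoint = 8, width = 1.5, lapse = 0.02, guess = 1 / 3)
  width_at <- function(n_per) {
    mean(vapply(1:4, function(i) {
      d <- simulate_psychometric_responses(obs, 2^(0:6), n_per,
                                           seed = 600 + i)
      th <- threshold_at(fit_psychometric(d, grid = FAST_GRID), 0.794)
      diff(unname(th$ci))
    }, numeric(1)))
  }
  expect_lt(width_at(80), width_at(20))
})

test_that("fits are invariant to rescaling the stimulus units", {
  obs <- observer_model(midpoint = 8, width = 1.5, lapse = 0, guess = 0.5)
  d <- simulate_psychometric_responses(obs, 2^(0:6), 50, seed = 9)
  scaled <- psychometric_data(d$levels * 1000, d$n_trials, d$n_correct,
                              d$guess)
  t1 <- threshold_at(fit_psychometric(d, grid = FAST_GRID), 0.75)
  t2 <- threshold_at(fit_psychometric(scaled, grid = FAST_GRID), 0.75)
  expect_equal(t2$threshold / t1$threshold, 1000, tolerance = 1e-6)
  expect_equal(unname(t2$ci / t1$ci), c(1000, 1000), tolerance = 1e-6)
})

test_that("CMR effects difference the condition thresholds with the release-positive sign", {
  expect_equal(cmr_effect(c(REF = -5, CORR = -5, ACORR = -5))$cmr_db, c(0, 0))
  # worked on the reported magnitudes: REF -10, CORR -14, ACORR +3
  eff <- cmr_effect(c(REF = -10, CORR = -14, ACORR = 3))
  expect_equal(eff$cmr_db[eff$comparison == "CORR-REF"], 4)
  expect_equal(eff$cmr_db[eff$comparison == "CORR-ACORR"], 17)
  # permutation of input order leaves outputs unchanged
  eff2 <- cmr_effect(c(ACORR = 3, REF = -10, CORR = -14))
  expect_equal(eff, eff2)
  expect_error(cmr_effect(c(REF = -10, CORR = -14)), "ACORR")
})

test_that("SNR dB / amplitude-ratio conversions invert each other", {
  snrs <- c(-16, -3, 0, 10)
  expect_equal(ratio_to_snr_db(snr_db_to_ratio(snrs)), snrs)
  expect_equal(snr_db_to_ratio(20), 10)
})
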