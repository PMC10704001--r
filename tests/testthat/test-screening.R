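test_that("headphone rule: 5-of-6 conjunction and the relaxed 4-of-6 variant", {
  std <- headphone_rule()
  expect_true(score_headphone_check(5, 6, std))
  expect_true(score_headphone_check(5, 5, std))
  expect_true(score_headphone_check(6, 6, std))
  expect_false(score_headphone_check(6, 4, std))
  expect_false(score_headphone_check(4, 6, std))
  expect_false(score_headphone_check(4, 4, std))
  relaxed <- headphone_rule(min_correct = 4)
  expect_true(score_headphone_check(4, 4, relaxed))
  expect_false(score_headphone_check(3, 6, relaxed))
  expect_error(score_headphone_check(7, 5, std), "\\[0, 6\\]")
  expect_error(score_headphone_check(-1, 5, std), "\\[0, 6\\]")
})

test_that("hearing classifier applies cutoffs, blur, and survey gates", {
  pass <- classify_hearing(c("10" = 100, "5" = 83, "0" = 75), blur_count = 0)
  expect_true(pass$passed)
  expect_length(pass$reasons, 0)
  # one-point violation at 5 dB
  f1 <- classify_hearing(c("10" = 100, "5" = 82, "0" = 100))
  expect_false(f1$passed)
  expect_equal(f1$reasons, "5 dB cutoff")
  # engagement filter: strictly more than two blur events fails
  f2 <- classify_hearing(c("10" = 100, "5" = 100, "0" = 100), blur_count = 3)
  expect_false(f2$passed)
  expect_equal(f2$reasons, "engagement")
  expect_true(classify_hearing(c("10" = 100, "5" = 100, "0" = 100),
                               blur_count = 2)$passed)
  # survey gates must be explicit denials
  f3 <- classify_hearing(c("10" = 100, "5" = 90, "0" = 80),
                         survey = c(hearing_loss = FALSE,
                                    neurological_disorder = TRUE,
                                    persistent_tinnitus = TRUE))
  expect_equal(f3$reasons, "survey:hearing_loss")
  # reasons accumulate across failed gates
  f4 <- classify_hearing(c("10" = 90, "5" = 50, "0" = 50), blur_count = 5,
                         survey = c(hearing_loss = TRUE))
  expect_setequal(f4$reasons,
                  c("10 dB cutoff", "5 dB cutoff", "0 dB cutoff",
                    "engagement", "survey:neurological_disorder",
                    "survey:persistent_tinnitus"))
  expect_error(classify_hearing(c("10" = 100, "5" = 90)), "missing scores")
})

test_that("classifier is monotone: better scores or fewer blurs never flip pass to fail", {
  set.seed(14)
  for (i in 1:50) {
    scores <- c("10" = runif(1, 60, 100), "5" = runif(1, 50, 100),
                "0" = runif(1, 40, 100))
    blur <- sample(0:4, 1)
    base <- classify_hearing(scores, blur)
    bump <- scores
    j <- sample(3, 1)
    bump[j] <- min(100, bump[j] + runif(1, 0, 20))
    improved <- classify_hearing(bump, max(0, blur - 1))
    if (base$passed) expect_true(improved$passed)
  }
  # a ceiling participant with no blur events always passes
  expect_true(classify_hearing(c("10" = 100, "5" = 100, "0" = 100), 0)$passed)
})

test_that("two-Gaussian population model implies the documented HL distribution", {
  m <- population_model(g = 2.05, sd_ratio = 3, nh_mean = 0, nh_sd = 1)
  expect_equal(m$pooled_sd, sqrt((1 + 9) / 2))
  expect_equal(m$hl_mean, -2.05 * sqrt(5))
  expect_equal(m$hl_sd, 3)
  expect_error(population_model(sd_ratio = 0), "> 0")
  mw <- population_model(pooling = "n_weighted", n_nh = 50, n_hl = 50)
  expect_equal(mw$pooled_sd, sqrt((49 * 1 + 49 * 9) / 98))
  expect_error(population_model(pooling = "n_weighted"), "requires")
})

test_that("expected HL exclusion: identity at g = 0 and Monte-Carlo agreement", {
  null_model <- population_model(g = 0, sd_ratio = 1)
  for (q in c(0.1, 0.35, 0.8)) {
    expect_equal(expected_hl_exclusion(null_model, q), q, tolerance = 1e-12)
  }
  m <- population_model(g = 2.05, sd_ratio = 3)
  # independent Monte-Carlo oracle
  set.seed(101)
  nh <- rnorm(2e5, m$nh_mean, m$nh_sd)
  hl <- rnorm(2e5, m$hl_mean, m$hl_sd)
  cutoff <- quantile(nh, 0.35, type = 7)
  expect_equal(expected_hl_exclusion(m, 0.35), mean(hl < cutoff),
               tolerance = 0.01, ignore_attr = TRUE)
  # monotone in nh_exclusion and in g
  grid <- seq(0.05, 0.95, 0.05)
  vals <- expected_hl_exclusion(m, grid)
  expect_true(all(diff(vals) > 0))
  by_g <- vapply(c(1, 2, 3), function(g) {
    expected_hl_exclusion(population_model(g = g, sd_ratio = 3), 0.35)
  }, numeric(1))
  expect_true(all(diff(by_g) > 0))
  expect_error(expected_hl_exclusion(m, 0), "strictly")
})

test_that("theoretical ROC satisfies curve invariants", {
  null_roc <- theoretical_roc(population_model(g = 0, sd_ratio = 1))
  expect_equal(null_roc$hl_exclusion, null_roc$nh_exclusion, tolerance = 1e-12)
  roc <- theoretical_roc(population_model(g = 2.05, sd_ratio = 3))
  expect_true(all(diff(roc$nh_exclusion) >= 0))
  expect_true(all(diff(roc$hl_exclusion) >= 0))
  expect_equal(roc$nh_exclusion[1], 0)
  expect_equal(roc$hl_exclusion[nrow(roc)], 1)
  # pointwise non-decreasing in g at fixed sd ratio
  g1 <- theoretical_roc(population_model(g = 1, sd_ratio = 3))
  g3 <- theoretical_roc(population_model(g = 3, sd_ratio = 3))
  expect_true(all(g3$hl_exclusion >= g1$hl_exclusion))
  expect_error(theoretical_roc(population_model(), numeric(0)), "empty")
})

test_that("cutoff derivation relaxes from the 65th percentile to the target", {
  # degenerate cohort: everyone at 100 everywhere -> zero exclusion
  ids <- sprintf("P%03d", 1:30)
  flat <- expand.grid(participant_id = ids, snr_db = c(10, 5, 0),
                      stringsAsFactors = FALSE)
  flat$percent_correct <- 100
  res <- derive_cutoffs(flat, 0.35)
  expect_equal(res$achieved_exclusion, 0)
  expect_equal(res$percentile, 65)
  # simulated NH cohort: relaxation trace is monotone non-increasing and
  # lands at/below the target
  sim <- simulate_cohort_scores(cohort_spec(n = 2000, seed = 77))
  res2 <- derive_cutoffs(sim$scores, 0.35)
  expect_true(all(diff(res2$trace$exclusion) <= 1e-12))
  expect_lte(res2$achieved_exclusion, 0.35)
  expect_s3_class(res2$rule, "screening_rule")
  expect_named(res2$rule$cutoffs, c("10", "5", "0"))
  # cohort floor
  small <- flat[flat$participant_id %in% ids[1:10], ]
  expect_error(derive_cutoffs(small, 0.35), ">= 20")
})
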