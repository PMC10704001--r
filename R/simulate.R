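#' Parametric simulated observer
#'
#' An observer whose probability of a correct response at stimulus value `x`
#' is `guess + (1 - guess - lapse) * S(log x; log(midpoint), width)` with the
#' same logistic sigmoid used by [fit_psychometric()]. This is exactly the
#' response model the beta-binomial fit assumes, so fit-then-recover round
#' trips are meaningful.
#'
#' @param midpoint Sigmoid midpoint in stimulus units (> 0).
#' @param width 5–95% width on the log-stimulus axis (> 0).
#' @param lapse Lapse rate in \[0, 1).
#' @param guess Guess rate in (0, 1).
#' @param blur_rate Expected browser blur events per task run (Poisson).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(midpoint, width, lapse = 0, guess = 1 / 3,
                           blur_rate = 0) {
  stopifnot(midpoint > 0, width > 0, lapse >= 0, lapse < 1,
            guess > 0, guess < 1, guess + lapse < 1, blur_rate >= 0)
  structure(list(midpoint = midpoint, width = width, lapse = lapse,
                 guess = guess, blur_rate = blur_rate),
            class = "observer_model")
}

#' Probability correct for an observer at given stimulus values
#' @param observer An [observer_model()].
#' @param levels Stimulus values (> 0), vectorised.
#' @return Probability of a correct response at each level.
#' @export
observer_prob <- function(observer, levels) {
  stopifnot(inherits(observer, "observer_model"))
  observer$guess + (1 - observer$guess - observer$lapse) *
    sigmoid_log(log(levels), log(observer$midpoint), observer$width)
}

#' True threshold of an observer at a target performance level
#'
#' Closed-form inversion of the observer's performance curve; the oracle
#' against which fitted thresholds are compared.
#'
#' @param observer An [observer_model()].
#' @param target_pc Target proportion correct.
#' @return Stimulus value at which the observer performs at `target_pc`.
#' @export
observer_threshold <- function(observer, target_pc) {
  f <- (target_pc - observer$guess) / (1 - observer$guess - observer$lapse)
  if (f <= 0 || f >= 1) stop("target_pc outside the observer's range")
  exp(log(observer$midpoint) +
        observer$width * stats::qlogis(f) / WIDTH_SCALE)
}

#' Simulate method-of-constant-stimuli responses
#'
#' Binomial draws from the observer's performance curve at each level.
#'
#' @param observer An [observer_model()].
#' @param levels Stimulus ladder (positive, strictly increasing).
#' @param trials_per_level Trials at each level (scalar or vector).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return A [psychometric_data()].
#' @export
simulate_psychometric_responses <- function(observer, levels,
                                            trials_per_level, seed = NULL) {
  if (any(levels <= 0)) stop("levels must be positive")
  if (any(trials_per_level < 1)) stop("trials_per_level must be >= 1")
  n <- rep_len(as.integer(trials_per_level), length(levels))
  p <- observer_prob(observer, levels)
  k <- with_seed(seed, stats::rbinom(length(levels), n, p))
  psychometric_data(levels, n, k, observer$guess)
}

#' Specification of a simulated screening cohort
#'
#' @param n Number of participants.
#' @param hl_fraction Fraction drawn from the hearing-loss score
#'   distribution.
#' @param model A [population_model()] on the percent-score scale (defaults
#'   to the meta-analytic parameters on an NH mean of 85, SD 5, where
#'   clipping to \[0, 100\] is negligible).
#' @param snrs SNR conditions for the per-SNR score map.
#' @param snr_slope Logistic slope (dB) of the per-SNR score map.
#' @param snr_jitter SD (dB) of per-SNR offset jitter around the
#'   participant's overall offset.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, hl_fraction = 0,
                        model = population_model(nh_mean = 85, nh_sd = 5),
                        snrs = c(10, 5, 0, -5), snr_slope = 2,
                        snr_jitter = 0.5, seed = 1) {
  stopifnot(n >= 1, hl_fraction >= 0, hl_fraction <= 1,
            inherits(model, "population_model"))
  structure(list(n = n, hl_fraction = hl_fraction, model = model,
                 snrs = snrs, snr_slope = snr_slope,
                 snr_jitter = snr_jitter, seed = seed),
            class = "cohort_spec")
}

#' Simulate a screening cohort's scores
#'
#' Each participant draws an overall score from their group's Gaussian (NH
#' or HL per the two-Gaussian [population_model()]), clipped to \[0, 100\].
#' Per-SNR word-recognition scores are derived through a monotone map:
#' a logistic in SNR whose horizontal offset is the participant's overall
#' score mapped through the NH quantile scale, plus small per-SNR jitter.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `participants` (data frame: `participant_id`,
#'   `group`, `score`) and `scores` (long data frame: `participant_id`,
#'   `snr_db`, `percent_correct`).
#' @export
simulate_cohort_scores <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$model
  with_seed(spec$seed, {
    n_hl <- round(spec$n * spec$hl_fraction)
    group <- c(rep("HL", n_hl), rep("NH", spec$n - n_hl))
    raw <- ifelse(group == "HL",
                  stats::rnorm(spec$n, m$hl_mean, m$hl_sd),
                  stats::rnorm(spec$n, m$nh_mean, m$nh_sd))
    score <- pmin(pmax(raw, 0), 100)
    ids <- sprintf("P%05d", seq_len(spec$n))
    # overall score -> SNR offset: z-score on the NH scale, better listeners
    # (higher score) tolerate lower SNRs (lower offset)
    z <- (raw - m$nh_mean) / m$nh_sd
    offset0 <- -2 - 2 * z
    long <- do.call(rbind, lapply(spec$snrs, function(s) {
      off <- offset0 + stats::rnorm(spec$n, 0, spec$snr_jitter)
      data.frame(participant_id = ids, snr_db = s,
                 percent_correct =
                   100 * stats::plogis((s - off) / spec$snr_slope),
                 stringsAsFactors = FALSE)
    }))
    list(
      participants = data.frame(participant_id = ids, group = group,
                                score = score, stringsAsFactors = FALSE),
      scores = long[order(long$participant_id, -long$snr_db), ]
    )
  })
}

#' Listening-setup response model for the headphone checks
#'
#' Per-task accuracy under the three listening setups the checks are built
#' to distinguish: stereo headphones do both tasks well; a mono earphone
#' leaves the triad easy but reduces the dichotic chirp task to chance
#' (no binaural release, and each channel alone hides the antiphase cue);
#' free-field speakers degrade the triad (the antiphase foil partially
#' cancels in the air and can sound softer than the target) and also leave
#' the chirp near chance.
#'
#' @param mode `"stereo"`, `"mono"`, or `"freefield"`.
#' @param triad_accuracy,chirp_accuracy Optional overrides of the per-task
#'   trial accuracies.
#' @return An object of class `listening_mode`.
#' @export
listening_mode <- function(mode = c("stereo", "mono", "freefield"),
                           triad_accuracy = NULL, chirp_accuracy = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    stereo = c(0.98, 0.95),
    mono = c(0.98, 1 / 3),
    freefield = c(0.40, 1 / 3)
  )
  acc <- c(
    triad = if (is.null(triad_accuracy)) defaults[1] else triad_accuracy,
    chirp = if (is.null(chirp_accuracy)) defaults[2] else chirp_accuracy
  )
  stopifnot(all(acc >= 0 & acc <= 1))
  structure(list(mode = mode, accuracy = acc), class = "listening_mode")
}

#' Simulate one headphone-screening session
#'
#' Draws 6 + 6 Bernoulli trial outcomes from the listening mode's per-task
#' accuracies and applies the headphone rule.
#'
#' @param mode A [listening_mode()].
#' @param rule A [headphone_rule()].
#' @param seed RNG seed (NULL = current RNG state).
#' @return A list: `triad_correct`, `chirp_correct` (counts), `passed`, and
#'   `fail_reasons` (character, among "triad", "chirp").
#' @export
simulate_headphone_session <- function(mode, rule = headphone_rule(),
                                       seed = NULL) {
  stopifnot(inherits(mode, "listening_mode"))
  with_seed(seed, {
    triad <- stats::rbinom(1, rule$n_trials, mode$accuracy["triad"])
    chirp <- stats::rbinom(1, rule$n_trials, mode$accuracy["chirp"])
    reasons <- c(if (triad < rule$min_correct) "triad",
                 if (chirp < rule$min_correct) "chirp")
    list(triad_correct = triad, chirp_correct = chirp,
         passed = length(reasons) == 0, fail_reasons = reasons)
  })
}

#' Empirical ROC curve from a simulated cohort
#'
#' Simulates a mixed NH/HL cohort, sweeps score cutoffs placed at the NH
#' group's empirical quantiles, and tallies NH and HL exclusion fractions —
#' the Monte-Carlo counterpart of [theoretical_roc()].
#'
#' @param spec A [cohort_spec()] with both groups present
#'   (`0 < hl_fraction < 1`).
#' @param grid NH-exclusion fractions to evaluate.
#' @return An object of class `roc_curve` (as [theoretical_roc()]).
#' @export
empirical_roc <- function(spec, grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$hl_fraction <= 0 || spec$hl_fraction >= 1) {
    stop("empirical_roc needs a mixed cohort (0 < hl_fraction < 1)")
  }
  sim <- simulate_cohort_scores(spec)
  nh <- sim$participants$score[sim$participants$group == "NH"]
  hl <- sim$participants$score[sim$participants$group == "HL"]
  grid <- sort(grid)
  pts <- vapply(grid, function(q) {
    cutoff <- as.numeric(stats::quantile(nh, q, type = 7))
    c(mean(nh < cutoff), mean(hl < cutoff))
  }, numeric(2))
  out <- data.frame(
    nh_exclusion = c(0, pts[1, ], 1),
    hl_exclusion = c(0, cummax(pts[2, ]), 1)
  )
  structure(out, class = c("roc_curve", "data.frame"))
}
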