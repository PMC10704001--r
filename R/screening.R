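#' Headphone-check decision rule
#'
#' Both headphone tasks (antiphase triad and dichotic chirp) run six trials;
#' the standard rule requires five correct in each, relaxed to four for
#' cohorts recruited for diagnosed hearing loss.
#'
#' @param n_trials Trials per task (6 as deployed).
#' @param min_correct Correct trials required per task (5 standard,
#'   4 relaxed).
#' @return An object of class `headphone_rule`.
#' @export
headphone_rule <- function(n_trials = 6, min_correct = 5) {
  stopifnot(min_correct <= n_trials, min_correct >= 0)
  structure(list(n_trials = n_trials, min_correct = min_correct),
            class = "headphone_rule")
}

#' Apply the headphone-check rule
#'
#' @param task1_correct,task2_correct Correct-trial counts for the antiphase
#'   triad task and the chirp-in-noise task.
#' @param rule A [headphone_rule()].
#' @return `TRUE` (pass) iff both counts reach `min_correct`.
#' @examples
#' score_headphone_check(5, 6)                          # pass
#' score_headphone_check(6, 4)                          # fail
#' score_headphone_check(4, 4, headphone_rule(min_correct = 4)) # relaxed pass
#' @export
score_headphone_check <- function(task1_correct, task2_correct,
                                  rule = headphone_rule()) {
  counts <- c(task1_correct, task2_correct)
  if (any(counts < 0) || any(counts > rule$n_trials)) {
    stop("correct counts must lie in [0, ", rule$n_trials, "]")
  }
  all(counts >= rule$min_correct)
}

#' Hearing-screening decision rule
#'
#' Per-SNR percent-correct cutoffs on the word-recognition-in-babble task
#' (compared with `>=`), an engagement limit on browser focus-loss ("blur")
#' events, and survey gates requiring explicit denial of hearing loss,
#' neurological disorders, and persistent tinnitus. Scores at -5 dB SNR are
#' recorded by the task but never gate.
#'
#' @param cutoffs Named numeric vector of percent-correct cutoffs keyed by
#'   SNR in dB. Defaults to the deployed rule: 100 at 10 dB, 83 at 5 dB,
#'   75 at 0 dB.
#' @param max_blur Maximum tolerated blur events (fail when strictly more).
#' @param survey_gates Character vector of survey items that must be denied.
#' @return An object of class `screening_rule`.
#' @export
screening_rule <- function(cutoffs = c("10" = 100, "5" = 83, "0" = 75),
                           max_blur = 2,
                           survey_gates = c("hearing_loss",
                                            "neurological_disorder",
                                            "persistent_tinnitus")) {
  if (any(cutoffs < 0 | cutoffs > 100)) stop("cutoffs must lie in [0, 100]")
  if (is.null(names(cutoffs))) stop("cutoffs must be named by SNR (dB)")
  structure(list(cutoffs = cutoffs, max_blur = max_blur,
                 survey_gates = survey_gates),
            class = "screening_rule")
}

#' Classify a participant's hearing status
#'
#' A participant passes iff they meet every per-SNR cutoff (score `>=`
#' cutoff), registered no more than `max_blur` blur events, and denied every
#' survey gate. The outcome enumerates every failed gate.
#'
#' @param scores_by_snr Named numeric vector of percent-correct scores keyed
#'   by SNR (dB); must cover every SNR in the rule's cutoffs.
#' @param blur_count Number of browser blur events during the task.
#' @param survey Named logical vector: `TRUE` means the participant denied
#'   the condition. Missing or `FALSE` entries fail the gate.
#' @param rule A [screening_rule()].
#' @return An object of class `screening_outcome`: `passed` flag and
#'   `reasons` (character vector of failed gates, empty iff passed).
#' @export
classify_hearing <- function(scores_by_snr, blur_count = 0,
                             survey = c(hearing_loss = TRUE,
                                        neurological_disorder = TRUE,
                                        persistent_tinnitus = TRUE),
                             rule = screening_rule()) {
  need <- names(rule$cutoffs)
  missing_snr <- setdiff(need, names(scores_by_snr))
  if (length(missing_snr)) {
    stop("missing scores for SNR(s): ", paste(missing_snr, collapse = ", "),
         " dB")
  }
  reasons <- character(0)
  for (snr in need) {
    if (scores_by_snr[[snr]] < rule$cutoffs[[snr]]) {
      reasons <- c(reasons, sprintf("%s dB cutoff", snr))
    }
  }
  if (blur_count > rule$max_blur) reasons <- c(reasons, "engagement")
  for (gate in rule$survey_gates) {
    denied <- gate %in% names(survey) && isTRUE(unname(survey[gate]))
    if (!denied) reasons <- c(reasons, sprintf("survey:%s", gate))
  }
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "screening_outcome")
}

#' @export
print.screening_outcome <- function(x, ...) {
  if (x$passed) cat("<screening_outcome> PASS\n")
  else cat("<screening_outcome> FAIL:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Two-Gaussian population model of screening-task scores
#'
#' Normal-hearing (NH) scores are Normal(`nh_mean`, `nh_sd`); hearing-loss
#' (HL) scores are Normal with standard deviation `sd_ratio * nh_sd` and
#' mean shifted down by `g` pooled standard deviations. The meta-analytic
#' calibration of the deployed screen uses g = 2.05 and sd_ratio = 3.
#'
#' @param g Standardized mean difference (pooled-SD units) between NH and HL.
#' @param sd_ratio HL SD divided by NH SD (> 0).
#' @param nh_mean,nh_sd NH score distribution parameters (score units).
#' @param pooling `"equal"` (default, `sqrt((s1^2 + s2^2) / 2)`) or
#'   `"n_weighted"` with `n_nh`, `n_hl` supplied.
#' @param n_nh,n_hl Group sizes for n-weighted pooling.
#' @return An object of class `population_model` including the implied
#'   `hl_mean`, `hl_sd`, and `pooled_sd`.
#' @export
population_model <- function(g = 2.05, sd_ratio = 3, nh_mean = 0, nh_sd = 1,
                             pooling = c("equal", "n_weighted"),
                             n_nh = NULL, n_hl = NULL) {
  pooling <- match.arg(pooling)
  if (sd_ratio <= 0) stop("sd_ratio must be > 0")
  if (nh_sd <= 0) stop("nh_sd must be > 0")
  hl_sd <- sd_ratio * nh_sd
  pooled_sd <- if (pooling == "equal") {
    sqrt((nh_sd^2 + hl_sd^2) / 2)
  } else {
    if (is.null(n_nh) || is.null(n_hl)) {
      stop("n-weighted pooling requires n_nh and n_hl")
    }
    sqrt(((n_nh - 1) * nh_sd^2 + (n_hl - 1) * hl_sd^2) / (n_nh + n_hl - 2))
  }
  structure(
    list(g = g, sd_ratio = sd_ratio, nh_mean = nh_mean, nh_sd = nh_sd,
         hl_mean = nh_mean - g * pooled_sd, hl_sd = hl_sd,
         pooled_sd = pooled_sd, pooling = pooling),
    class = "population_model"
  )
}

#' Expected HL exclusion at a given NH exclusion
#'
#' Places the score cutoff at the NH distribution's `nh_exclusion` quantile
#' and returns the probability mass of the HL distribution below it — the
#' screen's expected sensitivity at that operating point, computed
#' analytically from the two-Gaussian model.
#'
#' @param model A [population_model()].
#' @param nh_exclusion Fraction of NH participants excluded, in (0, 1)
#'   (vectorised).
#' @return Expected fraction of HL participants excluded.
#' @examples
#' expected_hl_exclusion(population_model(g = 2.05, sd_ratio = 3), 0.35)
#' @export
expected_hl_exclusion <- function(model, nh_exclusion) {
  stopifnot(inherits(model, "population_model"))
  if (any(nh_exclusion <= 0 | nh_exclusion >= 1)) {
    stop("nh_exclusion must lie strictly in (0, 1)")
  }
  cutoff <- stats::qnorm(nh_exclusion, model$nh_mean, model$nh_sd)
  stats::pnorm(cutoff, model$hl_mean, model$hl_sd)
}

#' Theoretical ROC curve of the two-Gaussian screen
#'
#' Evaluates [expected_hl_exclusion()] on a grid of NH-exclusion fractions
#' and returns the sensitivity/specificity trade-off curve, closed with the
#' (0, 0) and (1, 1) endpoints.
#'
#' @param model A [population_model()].
#' @param grid NH-exclusion fractions in (0, 1).
#' @return An object of class `roc_curve`: a data frame with columns
#'   `nh_exclusion`, `hl_exclusion`, non-decreasing in both.
#' @export
theoretical_roc <- function(model, grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(grid) == 0) stop("empty nh_exclusion grid")
  grid <- sort(grid)
  pts <- data.frame(
    nh_exclusion = c(0, grid, 1),
    hl_exclusion = c(0, expected_hl_exclusion(model, grid), 1)
  )
  structure(pts, class = c("roc_curve", "data.frame"))
}

#' Derive per-SNR screening cutoffs from a pilot cohort
#'
#' Implements the deployed calibration: initial cutoffs are placed at the
#' 65th percentile of the cohort's scores at each SNR (linear-interpolation
#' quantiles), then all cutoffs are relaxed simultaneously in 2-percentile
#' point steps until the joint exclusion — the fraction of the cohort
#' failing any per-SNR gate (`score < cutoff`) — first drops to at most
#' `target_exclusion`.
#'
#' @param cohort_scores Data frame with columns `participant_id`, `snr_db`,
#'   `percent_correct` (long format), covering every gate SNR per
#'   participant.
#' @param target_exclusion Target joint exclusion fraction in (0, 1)
#'   (0.35 as deployed).
#' @param gate_snrs SNRs (dB) that gate; -5 dB is recorded but never gates.
#' @param initial_percentile Starting percentile for the cutoffs.
#' @param step Percentile-point relaxation per step.
#' @param max_blur,survey_gates Passed through to the returned rule.
#' @return A list with `rule` (a [screening_rule()]), `achieved_exclusion`,
#'   `percentile` (final percentile used), and `trace` (data frame of the
#'   relaxation path).
#' @export
derive_cutoffs <- function(cohort_scores, target_exclusion = 0.35,
                           gate_snrs = c(10, 5, 0),
                           initial_percentile = 65, step = 2,
                           max_blur = 2,
                           survey_gates = c("hearing_loss",
                                            "neurological_disorder",
                                            "persistent_tinnitus")) {
  if (!(target_exclusion > 0 && target_exclusion < 1)) {
    stop("target_exclusion must lie in (0, 1)")
  }
  need_cols <- c("participant_id", "snr_db", "percent_correct")
  if (!all(need_cols %in% names(cohort_scores))) {
    stop("cohort_scores needs columns: ", paste(need_cols, collapse = ", "))
  }
  wide <- lapply(gate_snrs, function(s) {
    sub <- cohort_scores[cohort_scores$snr_db == s, ]
    sub <- sub[order(sub$participant_id), ]
    stats::setNames(sub$percent_correct, sub$participant_id)
  })
  ids <- names(wide[[1]])
  if (length(ids) < 20) stop("cohort must have >= 20 participants")
  if (!all(vapply(wide, function(v) identical(names(v), ids), logical(1)))) {
    stop("every participant needs a score at every gate SNR")
  }
  score_mat <- do.call(cbind, wide) # participants x gate SNRs

  exclusion_at <- function(pct) {
    cuts <- vapply(seq_along(gate_snrs), function(j) {
      as.numeric(stats::quantile(score_mat[, j], pct / 100, type = 7))
    }, numeric(1))
    fail <- rowSums(sweep(score_mat, 2, cuts, `<`) > 0) > 0
    list(cuts = cuts, exclusion = mean(fail))
  }

  pct <- initial_percentile
  trace <- data.frame(percentile = numeric(0), exclusion = numeric(0))
  repeat {
    res <- exclusion_at(pct)
    trace <- rbind(trace,
                   data.frame(percentile = pct, exclusion = res$exclusion))
    if (res$exclusion <= target_exclusion) break
    if (pct - step < 0) {
      stop(sprintf(
        "target exclusion %.2f unattainable; best achievable %.3f at the 0th percentile",
        target_exclusion, exclusion_at(0)$exclusion))
    }
    pct <- pct - step
  }
  cutoffs <- stats::setNames(res$cuts, as.character(gate_snrs))
  list(
    rule = screening_rule(cutoffs = cutoffs, max_blur = max_blur,
                          survey_gates = survey_gates),
    achieved_exclusion = res$exclusion,
    percentile = pct,
    trace = trace
  )
}
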