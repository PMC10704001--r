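#' Default configurations for the registered tasks
#'
#' Condition ladders follow the deployed designs: MRT word recognition at
#' SNRs 10, 5, 0, -5 dB (6AFC); F0-shift ladder 0.05–3.2 Hz, gap ladder
#' 1–32 ms, ITD ladder 2–128 us, all in geometric steps of 2 (3AFC for
#' F0/gap, 2AFC for ITD/ILD); ILD ladder 0.125–8 dB; CMR conditions REF,
#' CORR, ACORR over an SNR ladder; headphone checks with 6 trials each.
#'
#' @param task_id One of `"mrt"`, `"f0dl"`, `"gap"`, `"itd"`, `"ild"`,
#'   `"cmr"`, `"hp_triad"`, `"hp_bmld"`, `"consonant"`.
#' @return A named list: `task_id`, `condition_var`, `conditions`,
#'   `trials_per_condition`, `n_alternatives`, `choices`.
#' @export
task_config <- function(task_id) {
  switch(task_id,
    mrt = list(task_id = "mrt", condition_var = "snr_db",
               conditions = c(10, 5, 0, -5), trials_per_condition = 5,
               n_alternatives = 6,
               choices = paste0("word", 1:6)),
    f0dl = list(task_id = "f0dl", condition_var = "delta_f0",
                conditions = 0.05 * 2^(0:6), trials_per_condition = 10,
                n_alternatives = 3, choices = as.character(1:3)),
    gap = list(task_id = "gap", condition_var = "gap_ms",
               conditions = 2^(0:5), trials_per_condition = 10,
               n_alternatives = 3, choices = as.character(1:3)),
    itd = list(task_id = "itd", condition_var = "itd_us",
               conditions = 2 * 2^(0:6), trials_per_condition = 10,
               n_alternatives = 2, choices = c("LR", "RL")),
    ild = list(task_id = "ild", condition_var = "ild_db",
               conditions = 0.125 * 2^(0:6), trials_per_condition = 10,
               n_alternatives = 2, choices = c("LR", "RL")),
    cmr = list(task_id = "cmr", condition_var = "cmr_condition",
               conditions = c("REF", "CORR", "ACORR"),
               trials_per_condition = 10, n_alternatives = 3,
               choices = as.character(1:3)),
    hp_triad = list(task_id = "hp_triad", condition_var = "trial_type",
                    conditions = "standard", trials_per_condition = 6,
                    n_alternatives = 3, choices = as.character(1:3)),
    hp_bmld = list(task_id = "hp_bmld", condition_var = "trial_type",
                   conditions = "standard", trials_per_condition = 6,
                   n_alternatives = 3,
                   choices = c("rising", "falling", "flat")),
    consonant = list(task_id = "consonant", condition_var = "talker",
                     conditions = paste0("talker", 1:4),
                     trials_per_condition = 16, n_alternatives = 16,
                     choices = consonant_labels()),
    stop("unknown task '", task_id, "'")
  )
}

#' Build an ordered trial list for a task
#'
#' Expands the task's condition-by-trial design into a flat trial table,
#' assigns a correct choice to each trial, and shuffles the presentation
#' order deterministically under `seed`.
#'
#' @param config A [task_config()] (or a list with the same fields,
#'   allowing overrides such as `trials_per_condition`).
#' @param seed Integer seed controlling the trial order and correct-choice
#'   assignment; the same seed reproduces the identical list.
#' @return A data frame of trial specs: `trial_id`, `task_id`, the condition
#'   column (named by `condition_var`), `n_alternatives`, `correct_choice`,
#'   and `choices` (comma-joined label string).
#' @export
build_trial_list <- function(config, seed = 1) {
  need <- c("task_id", "condition_var", "conditions", "trials_per_condition",
            "n_alternatives", "choices")
  if (!all(need %in% names(config))) {
    stop("config must provide: ", paste(need, collapse = ", "))
  }
  if (length(config$choices) != config$n_alternatives) {
    stop("choices must have n_alternatives entries")
  }
  with_seed(seed, {
    grid <- expand.grid(condition = config$conditions,
                        rep = seq_len(config$trials_per_condition),
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    n <- nrow(grid)
    out <- data.frame(
      trial_id = sprintf("%s_%03d", config$task_id, seq_len(n)),
      task_id = config$task_id,
      condition = grid$condition,
      n_alternatives = config$n_alternatives,
      correct_choice = sample(config$choices, n, replace = TRUE),
      choices = paste(config$choices, collapse = ","),
      stringsAsFactors = FALSE
    )
    names(out)[names(out) == "condition"] <- config$condition_var
    rownames(out) <- NULL
    out
  })
}

#' Score response records against a trial list
#'
#' Joins responses to trials on `trial_id`, marks correctness against the
#' trial's `correct_choice`, and tabulates per-condition accuracy. Trials
#' without a response are reported as missing and excluded from the
#' denominator — never imputed.
#'
#' @param trials A [build_trial_list()] data frame.
#' @param records Data frame with columns `participant_id`, `trial_id`,
#'   `response`; an optional `correct` column is ignored and recomputed.
#' @return A data frame with one row per condition: the condition column,
#'   `n_trials`, `n_responded`, `n_correct`, `n_missing`, `percent_correct`.
#' @export
score_responses <- function(trials, records) {
  stopifnot(all(c("trial_id", "correct_choice") %in% names(trials)))
  stopifnot(all(c("trial_id", "response") %in% names(records)))
  unknown <- setdiff(records$trial_id, trials$trial_id)
  if (length(unknown)) {
    stop("responses reference unknown trial(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  dup <- records$trial_id[duplicated(records$trial_id)]
  if (length(dup)) {
    stop("duplicate responses for trial(s): ",
         paste(unique(dup), collapse = ", "))
  }
  cond_var <- setdiff(names(trials),
                      c("trial_id", "task_id", "n_alternatives",
                        "correct_choice", "choices"))[1]
  idx <- match(records$trial_id, trials$trial_id)
  records$correct <- records$response == trials$correct_choice[idx]
  records$condition <- trials[[cond_var]][idx]
  conditions <- unique(trials[[cond_var]])
  rows <- lapply(conditions, function(cv) {
    n_trials <- sum(trials[[cond_var]] == cv)
    sub <- records[records$condition == cv, , drop = FALSE]
    data.frame(
      condition = cv, n_trials = n_trials, n_responded = nrow(sub),
      n_correct = sum(sub$correct), n_missing = n_trials - nrow(sub),
      percent_correct = if (nrow(sub)) 100 * mean(sub$correct) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- cond_var
  out
}

#' A conditional study-flow rule
#'
#' Expresses the deployed study logic "present task B if the participant
#' scores more than X% in a condition of task A, else conclude and debrief".
#' The gate uses a strict inequality (score must exceed the threshold).
#'
#' @param source_task Task whose score gates the step.
#' @param condition Condition (value of the task's condition variable) whose
#'   score is examined.
#' @param threshold Percent-correct threshold in \[0, 100\].
#' @param next_task Task to present when the gate is taken, or `NA` to
#'   always conclude.
#' @return A list of class `flow_rule`.
#' @export
flow_rule <- function(source_task, condition, threshold, next_task) {
  if (threshold < 0 || threshold > 100) stop("threshold must lie in [0, 100]")
  structure(list(source_task = source_task, condition = condition,
                 threshold = threshold, next_task = next_task),
            class = "flow_rule")
}

#' Evaluate a chain of study-flow rules
#'
#' Walks an acyclic chain of [flow_rule()]s against per-task score tables,
#' emitting an ordered decision trace. A failed gate concludes the study
#' with a partial trajectory (flagged); a score exactly at a strict "more
#' than" threshold does not take the gate.
#'
#' @param rules List of [flow_rule()]s, evaluated as a chain starting from
#'   the first rule's `source_task`.
#' @param score_tables Named list (by task) of [score_responses()] tables.
#' @return A data frame trace with columns `task`, `condition`, `score`,
#'   `threshold`, `gate_taken`, `next_task`, plus attributes `completed`
#'   (logical: every gate passed) and `tasks_run`.
#' @export
evaluate_flow <- function(rules, score_tables) {
  chain <- vapply(rules, function(r) r$source_task, character(1))
  if (anyDuplicated(chain)) stop("cyclic flow rules: task revisited")
  nexts <- vapply(rules, function(r) as.character(r$next_task), character(1))
  for (i in seq_along(rules)) {
    if (!is.na(nexts[i]) && nexts[i] %in% chain[seq_len(i)]) {
      stop("cyclic flow rules: next_task points back into the chain")
    }
  }
  trace <- data.frame(task = character(0), condition = character(0),
                      score = numeric(0), threshold = numeric(0),
                      gate_taken = logical(0), next_task = character(0),
                      stringsAsFactors = FALSE)
  tasks_run <- character(0)
  completed <- TRUE
  for (r in rules) {
    tbl <- score_tables[[r$source_task]]
    if (is.null(tbl)) stop("no score table for task '", r$source_task, "'")
    cond_var <- names(tbl)[1]
    row <- tbl[tbl[[cond_var]] == r$condition, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("condition '", r$condition, "' not found for task '",
           r$source_task, "'")
    }
    score <- row$percent_correct
    taken <- score > r$threshold # strict "more than"
    trace <- rbind(trace, data.frame(
      task = r$source_task, condition = as.character(r$condition),
      score = score, threshold = r$threshold, gate_taken = taken,
      next_task = as.character(r$next_task), stringsAsFactors = FALSE
    ))
    tasks_run <- c(tasks_run, r$source_task)
    if (!taken) {
      completed <- FALSE
      break
    }
    if (!is.na(r$next_task)) tasks_run <- unique(c(tasks_run, r$next_task))
  }
  attr(trace, "completed") <- completed
  attr(trace, "tasks_run") <- tasks_run
  trace
}
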