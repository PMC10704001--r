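#' Read a trial-response CSV
#'
#' Responses are exchanged as plain CSV with required headers
#' `participant_id`, `trial_id`, `response`; optional columns `correct`
#' (logical/0-1) and `blur_count_running` (integer) are validated when
#' present.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_id", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("response file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if ("blur_count_running" %in% names(df)) {
    if (!is.numeric(df$blur_count_running) ||
        any(df$blur_count_running %% 1 != 0, na.rm = TRUE)) {
      stop("blur_count_running must be integer-valued")
    }
  }
  if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
  df
}

#' Read a cohort score CSV
#'
#' Long-format cohort scores with headers `participant_id`, `snr_db`,
#' `percent_correct`, as consumed by [derive_cutoffs()].
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_cohort_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "snr_db", "percent_correct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$percent_correct) ||
      any(df$percent_correct < 0 | df$percent_correct > 100)) {
    stop("percent_correct must be numeric in [0, 100]")
  }
  df
}

#' Serialize a screening rule to/from JSON
#' @param rule A [screening_rule()].
#' @param path Output (or input) JSON path.
#' @return `path` (write) or a [screening_rule()] (read).
#' @export
write_screening_rule <- function(rule, path) {
  stopifnot(inherits(rule, "screening_rule"))
  jsonlite::write_json(
    list(cutoffs = as.list(rule$cutoffs), max_blur = rule$max_blur,
         survey_gates = rule$survey_gates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screening_rule
#' @export
read_screening_rule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  screening_rule(cutoffs = unlist(x$cutoffs), max_blur = x$max_blur,
                 survey_gates = x$survey_gates)
}

#' Write a stimulus manifest
#'
#' Maps trial ids to stimulus files, conditions, and answer keys; the
#' structured-text companion of a directory of WAV files.
#'
#' @param trials A [build_trial_list()] data frame.
#' @param files Character vector of stimulus file names aligned with
#'   `trials`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest header (e.g.
#'   seeds, parameter overrides).
#' @return `path`, invisibly.
#' @export
write_stimulus_manifest <- function(trials, files, path, extra = list()) {
  stopifnot(nrow(trials) == length(files))
  manifest <- c(
    list(package = "audscreen",
         version = as.character(utils::packageVersion("audscreen")),
         n_trials = nrow(trials)),
    extra,
    list(trials = cbind(trials, file = files))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run-configuration container
#'
#' Validates a flat configuration against the set of known keys, so typos in
#' configuration files fail loudly, and computes a content hash that is
#' echoed into every artifact for provenance.
#'
#' @param ... Named configuration entries.
#' @param allowed Character vector of permitted keys.
#' @return An object of class `run_config` with a `hash` attribute.
#' @export
run_config <- function(...,
                       allowed = c("task", "seed", "out_dir", "mode",
                                   "snr_db", "target_exclusion", "n",
                                   "hl_fraction", "trials_per_condition",
                                   "target_pc", "linkage", "n_clusters")) {
  cfg <- list(...)
  if (length(cfg) && is.null(names(cfg))) stop("config entries must be named")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "run_config", hash = rlang::hash(cfg))
}

#' Execute a named pipeline command
#'
#' The programmatic core of the command-line interface: dispatches a
#' registered command with a validated [run_config()], writes its artifacts
#' under `config$out_dir`, and records a machine-readable run manifest
#' (versions, seed, parameters, config hash) next to them. Outputs are
#' deterministic under a fixed seed.
#'
#' @param name One of `"synth"`, `"build-trials"`, `"score"`,
#'   `"screen-headphone"`, `"screen-hearing"`, `"derive-cutoffs"`, `"roc"`,
#'   `"fit"`, `"effects"`, `"cluster"`, `"simulate"`.
#' @param config A [run_config()].
#' @param ... Command-specific inputs (e.g. `trials` and `records` for
#'   `"score"`, `data` for `"fit"`).
#' @return The command's primary result, invisibly; artifacts land in
#'   `config$out_dir`.
#' @export
run_command <- function(name, config, ...) {
  commands <- c("synth", "build-trials", "score", "screen-headphone",
                "screen-hearing", "derive-cutoffs", "roc", "fit",
                "effects", "cluster", "simulate")
  if (!name %in% commands) {
    stop("unknown command '", name, "'; registered: ",
         paste(commands, collapse = ", "))
  }
  stopifnot(inherits(config, "run_config"))
  extra <- list(...)
  out_dir <- config$out_dir %||% tempfile("audscreen_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  result <- switch(name,
    "synth" = {
      task <- config$task %||% stop("synth requires config$task")
      cal <- make_calibration_sound(task, seed = seed)
      write_wav(cal$waveform, file.path(out_dir, paste0(task, "_cal.wav")))
      cal
    },
    "build-trials" = {
      task <- config$task %||% stop("build-trials requires config$task")
      cfg <- task_config(task)
      if (!is.null(config$trials_per_condition)) {
        cfg$trials_per_condition <- config$trials_per_condition
      }
      trials <- build_trial_list(cfg, seed = seed)
      utils::write.csv(trials, file.path(out_dir, paste0(task, "_trials.csv")),
                       row.names = FALSE)
      trials
    },
    "score" = {
      tbl <- score_responses(extra$trials, extra$records)
      utils::write.csv(tbl, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)
      tbl
    },
    "screen-headphone" = {
      score_headphone_check(extra$task1_correct, extra$task2_correct,
                            extra$rule %||% headphone_rule())
    },
    "screen-hearing" = {
      classify_hearing(extra$scores_by_snr, extra$blur_count %||% 0,
                       extra$survey %||% c(hearing_loss = TRUE,
                                           neurological_disorder = TRUE,
                                           persistent_tinnitus = TRUE),
                       extra$rule %||% screening_rule())
    },
    "derive-cutoffs" = {
      res <- derive_cutoffs(extra$cohort_scores,
                            config$target_exclusion %||% 0.35)
      write_screening_rule(res$rule, file.path(out_dir, "screening_rule.json"))
      res
    },
    "roc" = {
      model <- extra$model %||% population_model()
      roc <- theoretical_roc(model)
      utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
      roc
    },
    "fit" = {
      fit <- fit_psychometric(extra$data,
                              extra$priors %||% psychometric_priors(),
                              extra$grid %||% grid_config())
      thr <- threshold_at(fit, config$target_pc %||% 0.794)
      jsonlite::write_json(
        list(estimate = as.list(fit$estimate), boundary = fit$boundary,
             threshold = thr$threshold, ci = as.list(thr$ci),
             target_pc = thr$target_pc),
        file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
      list(fit = fit, threshold = thr)
    },
    "effects" = {
      eff <- hedges_g(extra$a, extra$b, extra$pooling %||% "equal")
      jsonlite::write_json(unclass(eff), file.path(out_dir, "effect.json"),
                           auto_unbox = TRUE, digits = NA)
      eff
    },
    "cluster" = {
      part <- cluster_confusions(extra$matrix, config$n_clusters %||% 9,
                                 config$linkage %||% "average")
      jsonlite::write_json(
        list(clusters = part$clusters, threshold = part$threshold,
             merge_heights = part$merge_heights, linkage = part$linkage),
        file.path(out_dir, "partition.json"), auto_unbox = TRUE, digits = NA)
      part
    },
    "simulate" = {
      spec <- cohort_spec(n = config$n %||% 1000,
                          hl_fraction = config$hl_fraction %||% 0,
                          seed = seed)
      sim <- simulate_cohort_scores(spec)
      utils::write.csv(sim$scores, file.path(out_dir, "cohort_scores.csv"),
                       row.names = FALSE)
      sim
    }
  )

  manifest <- list(
    command = name,
    package = "audscreen",
    version = as.character(utils::packageVersion("audscreen")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = unclass(config),
    config_hash = attr(config, "hash"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
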