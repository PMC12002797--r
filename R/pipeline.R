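#' Pipeline run configuration
#'
#' Collects everything a full run needs: input mode (synthetic or CSV paths),
#' the cohort configuration, fitting options, statistics options, the master
#' seed and the output directory. The seed and a configuration hash are
#' recorded in every emitted artifact.
#'
#' @param mode `"synthetic"` (default) or `"files"`.
#' @param paths For `mode = "files"`: named list with `stimuli`,
#'   `perception_trials`, `altruism_trials` CSV paths.
#' @param n_subjects Cohort size in synthetic mode.
#' @param cohort A [cohort_config()].
#' @param restarts,shrinkage Fitting options passed to the cohort fitters.
#' @param alpha Significance level used in the text report.
#' @param seed Master seed (required).
#' @param out_dir Output directory (`NULL` to skip writing artifacts).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), paths = NULL,
                            n_subjects = 25, cohort = cohort_config(),
                            restarts = 8, shrinkage = FALSE, alpha = 0.05,
                            seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(paths)) {
    abort('`paths` is required when mode = "files".', class = "socialddm_input_error")
  }
  structure(list(mode = mode, paths = paths, n_subjects = n_subjects,
                 cohort = cohort, restarts = restarts, shrinkage = shrinkage,
                 alpha = alpha, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Validate input trial tables
#'
#' Schema, range and invariant checks for the stimulus and trial tables.
#' Hard violations (missing columns, negative RTs, unknown condition levels)
#' raise an error when `strict = TRUE`; soft issues (need cues outside the
#' jitter bands) are reported as warnings in the returned table.
#'
#' @param tables Named list with any of `stimuli`, `perception_trials`,
#'   `altruism_trials`.
#' @param strict Error on hard violations (default `TRUE`).
#' @return Tibble with `table`, `severity` (`"hard"`/`"soft"`), `message`;
#'   zero rows when everything passes.
#' @export
validate_inputs <- function(tables, strict = TRUE) {
  issues <- list()
  note <- function(tbl, severity, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(table = tbl,
                                                    severity = severity,
                                                    message = msg)
  }
  if (!is.null(tables$stimuli)) {
    st <- tables$stimuli
    need_cols <- c("stimulus_id", "merit_prop", "need_prop", "control_prop")
    miss <- setdiff(need_cols, names(st))
    if (length(miss)) note("stimuli", "hard", paste("missing columns:",
                                                    paste(miss, collapse = ", ")))
    else if (any(st$merit_prop < 0 | st$merit_prop > 1 |
                 st$need_prop < 0 | st$need_prop > 1 |
                 st$control_prop < 0 | st$control_prop > 1)) {
      note("stimuli", "hard", "proportions outside [0, 1]")
    }
  }
  if (!is.null(tables$perception_trials)) {
    pt <- tables$perception_trials
    need_cols <- c("subject_id", "stimulus_id", "condition", "response", "rt")
    miss <- setdiff(need_cols, names(pt))
    if (length(miss)) note("perception_trials", "hard",
                           paste("missing columns:", paste(miss, collapse = ", ")))
    else {
      if (any(pt$rt <= 0, na.rm = TRUE)) note("perception_trials", "hard",
                                              "non-positive rt values")
      bad <- setdiff(unique(pt$condition), perception_conditions)
      if (length(bad)) note("perception_trials", "hard",
                            paste("unknown condition:", paste(bad, collapse = ", ")))
      bad <- setdiff(unique(stats::na.omit(pt$response)), c("yes", "no"))
      if (length(bad)) note("perception_trials", "hard",
                            paste("unknown response:", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(tables$altruism_trials)) {
    at <- tables$altruism_trials
    need_cols <- c("subject_id", "partner_merit", "need_level", "need_cue_pct",
                   "offer_self", "offer_other", "response", "rt")
    miss <- setdiff(need_cols, names(at))
    if (length(miss)) note("altruism_trials", "hard",
                           paste("missing columns:", paste(miss, collapse = ", ")))
    else {
      if (any(at$rt <= 0, na.rm = TRUE)) note("altruism_trials", "hard",
                                              "non-positive rt values")
      bad <- setdiff(unique(at$partner_merit), merit_levels)
      if (length(bad)) note("altruism_trials", "hard",
                            paste("unknown merit level:", paste(bad, collapse = ", ")))
      bad <- setdiff(unique(at$need_level), need_levels)
      if (length(bad)) note("altruism_trials", "hard",
                            paste("unknown need level:", paste(bad, collapse = ", ")))
      if (any(at$offer_self < 0 | at$offer_other < 0, na.rm = TRUE)) {
        note("altruism_trials", "hard", "negative offers")
      }
      in_band <- (at$need_cue_pct >= 76 & at$need_cue_pct <= 84) |
        (at$need_cue_pct >= 16 & at$need_cue_pct <= 24)
      if (any(!in_band, na.rm = TRUE)) {
        note("altruism_trials", "soft",
             "need cues outside the 80 +/- 4 / 20 +/- 4 jitter bands")
      }
    }
  }
  out <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(table = character(), severity = character(),
                   message = character())
  }
  if (strict && any(out$severity == "hard")) {
    abort(paste0("input validation failed:\n  ",
                 paste(sprintf("[%s] %s", out$table[out$severity == "hard"],
                               out$message[out$severity == "hard"]),
                       collapse = "\n  ")),
          class = "socialddm_input_error")
  }
  if (any(out$severity == "soft")) {
    warn(paste("soft validation issues:",
               paste(out$message[out$severity == "soft"], collapse = "; ")))
  }
  out
}

#' Assemble the per-subject linked dataset
#'
#' Joins the perception summaries, altruism change scores, generosity change
#' scores and subject covariates into one row per subject, flagging subjects
#' missing either task.
#'
#' @param perception_fits A [fit_perception()] tibble.
#' @param altruism_fits A [fit_altruism()] tibble.
#' @param gen_changes A [generosity_change_scores()] tibble.
#' @param subjects Optional tibble with `subject_id`, `rtpj_beta`,
#'   `inter_task_delay_days`.
#' @return Tibble, one row per subject, with a `complete` flag.
#' @export
build_linked_dataset <- function(perception_fits, altruism_fits, gen_changes,
                                 subjects = NULL) {
  per <- dplyr::select(perception_fits, -dplyr::any_of(c("fit", "loglik", "converged")))
  alt <- dplyr::select(altruism_fits, -dplyr::any_of(c("fit", "loglik", "converged")))
  out <- dplyr::full_join(per, alt, by = "subject_id") |>
    dplyr::full_join(gen_changes, by = "subject_id")
  if (!is.null(subjects)) out <- dplyr::left_join(out, subjects, by = "subject_id")
  out$complete <- stats::complete.cases(
    out[c("S_merit", "dw_other_merit", "dgen_merit")])
  if (any(!out$complete)) warn("some subjects are missing one of the tasks.")
  out
}

#' Cross-task correlation battery
#'
#' The individual-differences grid linking perception to action: merit/need
#' sensitivities against the matching generosity and weight change scores,
#' and merit/need biases against overall generosity and overall weights; one
#' Benjamini-Hochberg family per battery, mirroring the analysis structure of
#' the study the package models.
#'
#' @param linked A [build_linked_dataset()] tibble.
#' @return Named list of [spearman_fdr()] tibbles: `sanity` (change scores vs
#'   weight changes), `sensitivity` and `bias` batteries.
#' @export
cross_task_correlations <- function(linked) {
  linked <- linked[linked$complete, ]
  list(
    sanity = spearman_fdr(linked, list(
      c("dgen_merit", "dw_self_merit"), c("dgen_merit", "dw_other_merit"),
      c("dgen_merit", "dw_fairness_merit"), c("dgen_need", "dw_self_need"),
      c("dgen_need", "dw_other_need"), c("dgen_need", "dw_fairness_need"))),
    sensitivity = spearman_fdr(linked, list(
      c("S_merit", "dgen_merit"), c("S_merit", "dw_other_merit"),
      c("S_merit", "dw_self_merit"), c("S_merit", "dw_fairness_merit"),
      c("S_need", "dgen_need"), c("S_need", "dw_other_need"),
      c("S_need", "dw_self_need"), c("S_need", "dw_fairness_need"))),
    bias = spearman_fdr(linked, list(
      c("Bias_merit", "overall_generosity"), c("Bias_merit", "overall_w_other"),
      c("Bias_merit", "overall_w_self"), c("Bias_merit", "overall_w_fairness"),
      c("Bias_need", "overall_generosity"), c("Bias_need", "overall_w_other"),
      c("Bias_need", "overall_w_self"), c("Bias_need", "overall_w_fairness")))
  )
}

#' Run the full pipeline
#'
#' Generate (or load) both tasks' data, fit both computational models,
#' compute generosity metrics, and run the linking statistics, optionally
#' writing per-subject parameter JSONs, the subject-summary and generosity
#' CSVs, a statistics JSON and a text report to `config$out_dir`. Idempotent
#' given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate products: data, fits,
#'   metrics, linked dataset and statistics.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- "data"
  result <- tryCatch({
    if (config$mode == "synthetic") {
      cohort <- generate_linked_cohort(config$n_subjects, config$cohort)
      stimuli <- generate_normative_stimuli(64, config$cohort)
      perception_trials <- generate_perception_dataset(cohort$perception_truth,
                                                      stimuli, config$cohort)
      altruism_trials <- generate_altruism_dataset(cohort$altruism_truth)
      subjects <- cohort$subjects
      truth <- cohort
    } else {
      stimuli <- center_stimuli(utils::read.csv(config$paths$stimuli))
      perception_trials <- utils::read.csv(config$paths$perception_trials)
      altruism_trials <- utils::read.csv(config$paths$altruism_trials)
      subjects <- NULL
      truth <- NULL
    }
    validate_inputs(list(stimuli = stimuli,
                         perception_trials = perception_trials,
                         altruism_trials = altruism_trials))

    stage <- "fit-perception"
    perception_fits <- fit_perception(perception_trials, stimuli,
                                      restarts = config$restarts,
                                      shrinkage = config$shrinkage)
    stage <- "fit-altruism"
    altruism_fits <- fit_altruism(altruism_trials, restarts = config$restarts,
                                  shrinkage = config$shrinkage)
    stage <- "metrics"
    gen_table <- generosity_fractions(altruism_trials)
    gen_changes <- generosity_change_scores(gen_table)
    qc <- qc_exclusions(altruism_trials)

    stage <- "link"
    linked <- build_linked_dataset(perception_fits, altruism_fits, gen_changes,
                                   subjects)
    stats_out <- list(
      glmm = glance(fit_generosity_glmm(altruism_trials)),
      contrasts = weight_condition_contrasts(altruism_fits),
      correlations = cross_task_correlations(linked)
    )
    if (!is.null(subjects)) {
      ld <- linked[linked$complete, ]
      stats_out$linking_regression <- glance(
        linking_regression(ld$dw_other_merit, ld$S_merit, ld$rtpj_beta))
      if (nrow(ld) >= 6) {
        stats_out$partial_delay <- partial_spearman(
          ld$S_merit, ld$dw_other_merit, ld$inter_task_delay_days)
      }
    }
    list(stimuli = stimuli, perception_trials = perception_trials,
         altruism_trials = altruism_trials, truth = truth,
         perception_fits = perception_fits, altruism_fits = altruism_fits,
         generosity = gen_table, generosity_changes = gen_changes, qc = qc,
         linked = linked, statistics = stats_out)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "socialddm_pipeline_error", parent = e)
  })

  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(result, config)
  }
  invisible(result)
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, restarts = config$restarts,
               config_hash = rlang::hash(unclass(config)[
                 setdiff(names(unclass(config)), c("out_dir", "paths"))]))
  par_dir <- file.path(config$out_dir, "params")
  dir.create(par_dir, showWarnings = FALSE)
  purrr::walk2(result$perception_fits$subject_id, result$perception_fits$fit,
               function(sid, f) {
                 write_perception_params(
                   f$params, file.path(par_dir, paste0(sid, "_perception.json")),
                   meta = c(meta, loglik = f$loglik))
               })
  purrr::walk2(result$altruism_fits$subject_id, result$altruism_fits$fit,
               function(sid, f) {
                 write_altruism_params(
                   f$params, file.path(par_dir, paste0(sid, "_altruism.json")),
                   meta = c(meta, loglik = f$loglik))
               })
  utils::write.csv(result$linked, file.path(config$out_dir, "subject_summary.csv"),
                   row.names = FALSE)
  write_generosity_csv(result$generosity,
                       file.path(config$out_dir, "generosity.csv"))
  jsonlite::write_json(c(meta, result$statistics),
                       file.path(config$out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report <- c(
    sprintf("socialddm pipeline report (seed %d, config %s)", config$seed,
            meta$config_hash),
    "",
    "Generosity fractions (cohort means):",
    utils::capture.output(print(as.data.frame(
      result$generosity |>
        dplyr::group_by(.data$merit, .data$need) |>
        dplyr::summarise(fraction = mean(.data$fraction, na.rm = TRUE),
                         .groups = "drop")), digits = 3)),
    "",
    "Weight condition contrasts (Wilcoxon, BH-adjusted):",
    utils::capture.output(print(as.data.frame(result$statistics$contrasts),
                                digits = 3)),
    "",
    "Cross-task Spearman batteries (BH-adjusted within battery):",
    utils::capture.output(print(as.data.frame(
      dplyr::bind_rows(result$statistics$correlations, .id = "battery")),
      digits = 3))
  )
  writeLines(report, file.path(config$out_dir, "report.txt"))
  invisible(config$out_dir)
}
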