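#' Build and validate a pipeline run configuration
#'
#' Assembles the configuration for an end-to-end run — experiment design,
#' perturbation schedule, simulator parameters, and master seed — from a
#' nested list (or a JSON file with the same structure), applying defaults
#' for anything omitted and validating the result. Validation failures name
#' the offending field.
#'
#' @param config A nested list, or a path to a JSON file. Recognised
#'   sections: `design` (`n_sentences`, `n_blocks`, `sync_start_block`,
#'   `n_congruent`, `n_incongruent`), `perturbation` (`magnitude_mel`,
#'   `angle_deg`, `ramp_block`, `ramp_trials`, `hold_end_block`,
#'   `off_block`), `profiles` (any [participant_profile()] dynamics
#'   parameter), and `seed`.
#' @return An object of class `run_config`: list with `design` (an
#'   [experiment_design()]), `profiles`, and `seed`.
#' @examples
#' run_config(list(seed = 7, profiles = list(conv_asymptote = 0.5)))
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  stopifnot(is.list(config))
  known <- c("design", "perturbation", "profiles", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop(sprintf("unknown config field: '%s'", extra[1]), call. = FALSE)
  }
  pert_args <- config$perturbation
  pert <- tryCatch({
    shift <- shift_vector(pert_args$magnitude_mel %||% 70,
                          pert_args$angle_deg %||% 315)
    do.call(perturbation_spec, c(
      list(shift = shift),
      pert_args[setdiff(names(pert_args), c("magnitude_mel", "angle_deg"))]))
  }, error = function(e) {
    stop(sprintf("config field 'perturbation': %s", conditionMessage(e)),
         call. = FALSE)
  })
  design <- tryCatch(
    do.call(experiment_design, c(list(perturbation = pert), config$design)),
    error = function(e) {
      stop(sprintf("config field 'design': %s", conditionMessage(e)),
           call. = FALSE)
    })
  profiles <- config$profiles %||% list()
  allowed <- c("conv_asymptote", "conv_rate", "retention", "learning_rate",
               "trial_noise_sd", "sentence_effect_sd")
  bad <- setdiff(names(profiles), allowed)
  if (length(bad)) {
    stop(sprintf("config field 'profiles.%s' is not a simulator parameter",
                 bad[1]), call. = FALSE)
  }
  seed <- config$seed %||% 1
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop("config field 'seed' must be an integer", call. = FALSE)
  }
  structure(list(design = design, profiles = profiles,
                 seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_as_list <- function(cfg) {
  d <- cfg$design
  p <- d$perturbation
  list(
    design = list(n_sentences = d$n_sentences, n_blocks = d$n_blocks,
                  sync_start_block = d$sync_start_block,
                  n_congruent = d$n_congruent,
                  n_incongruent = d$n_incongruent),
    perturbation = list(magnitude_mel = p$shift$magnitude,
                        angle_deg = p$shift$angle_deg,
                        ramp_block = p$ramp_block,
                        ramp_trials = p$ramp_trials,
                        hold_end_block = p$hold_end_block,
                        off_block = p$off_block),
    profiles = cfg$profiles,
    seed = cfg$seed
  )
}

round_cols <- function(df, cols, digits = 3) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read a trial table written by the pipeline
#'
#' @param path Path to a `trials.csv` in the pipeline's schema.
#' @return Data.frame with typed columns.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character",
                                 group = "character", block = "integer",
                                 trial_in_block = "integer",
                                 sentence_id = "integer",
                                 f1_mel = "numeric", f2_mel = "numeric",
                                 phase = "character"))
}

#' Run the full simulate-analyze-report pipeline
#'
#' Executes the pipeline stages in order into a run directory:
#'
#' * **simulate** — [simulate_cohort()] under the config's design and seed,
#'   writing `trials.csv` and `ground_truth.csv`;
#' * **analyze** — per-participant block-wise adaptation
#'   ([blockwise_adaptation()]) and baseline-window convergence plus
#'   congruency scores, written under `metrics/`;
#' * **report** — adapter/follower classification counts
#'   ([classify_cohort()]), group-mean adaptation curves, and the
#'   block-by-group mixed-model contrast ([group_contrast_lmm()]), written
#'   under `report/`.
#'
#' The resolved configuration is written alongside the outputs, a run log
#' records stage boundaries and skipped-trial counts, and a rerun into the
#' same directory resumes from an existing `trials.csv` rather than
#' re-simulating (set `overwrite = TRUE` to force a fresh simulation).
#' Formant and score columns are rounded to 3 decimals on disk; full
#' precision is kept in the returned objects.
#'
#' @param config A [run_config()] (or the list/path accepted by it).
#' @param out_dir Run directory (created if needed).
#' @param overwrite Re-simulate even when `trials.csv` exists.
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with the run directory, the trial table, the
#'   metrics tables, and the report objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir, overwrite = FALSE,
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "report"), showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  jsonlite::write_json(config_as_list(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  design <- config$design
  spec <- design$perturbation
  trials_path <- file.path(out_dir, "trials.csv")
  truth <- NULL
  if (file.exists(trials_path) && !overwrite) {
    logmsg("simulate: resuming from existing %s", trials_path)
    trials <- read_trials(trials_path)
  } else {
    logmsg("simulate: cohort of %d + %d participants, seed %d",
           design$n_congruent, design$n_incongruent, config$seed)
    cohort <- simulate_cohort(design, master_seed = config$seed,
                              profile_args = config$profiles)
    trials <- cohort$trials
    truth <- cohort$truth
    write_stage_csv(round_cols(trials, c("f1_mel", "f2_mel")), trials_path)
    write_stage_csv(
      round_cols(cohort$truth, c("target_f1_mel", "target_f2_mel",
                                 "state_f1_mel", "state_f2_mel", "gamma"),
                 digits = 4),
      file.path(out_dir, "ground_truth.csv"))
  }

  ids <- unique(trials$participant_id)
  logmsg("analyze: block-wise adaptation for %d participants", length(ids))
  ba <- do.call(rbind, lapply(ids, function(id) {
    b <- blockwise_adaptation(trials, id, spec)
    skipped <- attr(b, "n_skipped")
    if (skipped > 0) logmsg("analyze: %s: %d trials without baseline sentence skipped",
                            id, skipped)
    cbind(participant_id = id,
          group = trials$group[match(id, trials$participant_id)], b)
  }))
  conv <- do.call(rbind, lapply(ids, function(id) {
    cc <- convergence_change(trials, id)
    data.frame(participant_id = id,
               group = trials$group[match(id, trials$participant_id)],
               dF1 = cc[["dF1"]], dF2 = cc[["dF2"]],
               congruency = congruency_score(cc[["dF1"]], cc[["dF2"]], spec),
               stringsAsFactors = FALSE)
  }))
  write_stage_csv(round_cols(ba, "adaptation"),
                  file.path(out_dir, "metrics", "blockwise_adaptation.csv"))
  write_stage_csv(round_cols(conv, c("dF1", "dF2", "congruency")),
                  file.path(out_dir, "metrics", "convergence.csv"))

  logmsg("report: classification and group contrast")
  cls <- classify_cohort(trials, spec)
  counts <- as.data.frame.matrix(cls$counts)
  counts <- cbind(group = rownames(counts), counts)
  write_stage_csv(counts,
                  file.path(out_dir, "report", "classification_counts.csv"))
  curves <- stats::aggregate(adaptation ~ group + block, data = ba, FUN = mean)
  curves <- curves[order(curves$group, curves$block), ]
  write_stage_csv(round_cols(curves, "adaptation"),
                  file.path(out_dir, "report", "adaptation_curves.csv"))

  contrast <- NULL
  if (length(unique(trials$group)) > 1) {
    sc <- cohort_adaptation_scores(trials, spec)
    contrast <- group_contrast_lmm(sc)
    jsonlite::write_json(
      list(interaction = as.list(contrast$interaction),
           fixed_effects = cbind(term = rownames(contrast$coefficients),
                                 as.data.frame(contrast$coefficients)),
           simplified_random_structure = contrast$simplified),
      file.path(out_dir, "report", "group_contrast.json"),
      auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", digits = 6)
  }
  logmsg("done: outputs in %s", out_dir)
  writeLines(log_lines, log_path)
  invisible(list(out_dir = out_dir, trials = trials, truth = truth,
                 blockwise = ba, convergence = conv,
                 classification = cls, contrast = contrast))
}

#' Plot group-mean adaptation across blocks
#'
#' Mean adaptation score per block and group with across-participant
#' standard-error ribbons, from a pipeline `blockwise` table. Requires
#' ggplot2.
#'
#' @param blockwise Data.frame as produced by [run_pipeline()]'s analyze
#'   stage (`participant_id`, `group`, `block`, `adaptation`).
#' @return A ggplot object.
#' @export
plot_adaptation <- function(blockwise) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  agg <- stats::aggregate(adaptation ~ group + block, data = blockwise,
                          FUN = function(x) c(mean = mean(x),
                                              se = stats::sd(x) / sqrt(length(x))))
  agg <- cbind(agg[c("group", "block")], as.data.frame(agg$adaptation))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$block, y = .data$mean,
                                    colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$group),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Block", y = "Adaptation (mels)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}
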