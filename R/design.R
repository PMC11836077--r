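#' Experiment design for a synchronous-speech adaptation study
#'
#' The default design mirrors the blocked sentence-reading paradigm: 50
#' sentences read once per block across 7 blocks (350 trials per
#' participant), solo speech in block 1, synchronous speech with a
#' pre-recorded accompanist from block 2 on, and a feedback perturbation
#' following [perturbation_spec()]'s ramp/hold/off schedule.
#'
#' @param n_sentences Sentences per block.
#' @param n_blocks Number of blocks.
#' @param sync_start_block First block with the accompanist voice.
#' @param perturbation A [perturbation_spec()].
#' @param n_congruent,n_incongruent Group sizes for simulated cohorts.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(n_sentences = 50,
                              n_blocks = 7,
                              sync_start_block = 2,
                              perturbation = perturbation_spec(),
                              n_congruent = 16,
                              n_incongruent = 15) {
  stopifnot(inherits(perturbation, "perturbation_spec"))
  for (nm in c("n_sentences", "n_blocks", "sync_start_block",
               "n_congruent", "n_incongruent")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (perturbation$off_block > n_blocks) {
    stop("`off_block` exceeds `n_blocks`", call. = FALSE)
  }
  if (sync_start_block > n_blocks) {
    stop("`sync_start_block` exceeds `n_blocks`", call. = FALSE)
  }
  structure(
    list(n_sentences = as.integer(n_sentences),
         n_blocks = as.integer(n_blocks),
         sync_start_block = as.integer(sync_start_block),
         perturbation = perturbation,
         n_congruent = as.integer(n_congruent),
         n_incongruent = as.integer(n_incongruent)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d sentences x %d blocks (%d trials); sync from block %d; groups %d congruent / %d incongruent\n",
              x$n_sentences, x$n_blocks, x$n_sentences * x$n_blocks,
              x$sync_start_block, x$n_congruent, x$n_incongruent))
  print(x$perturbation)
  invisible(x)
}

#' Default group parameters for simulated cohorts
#'
#' Per-group baseline formant distributions (observed group means and SDs in
#' mels for female speakers of Canadian English) and the accompanist voice
#' each group hears. The congruent group's accompanist sits at lower F1 /
#' higher F2 than the group baseline (built by shifting a base voice 190
#' mels at 100 degrees), so converging toward it moves formants in the same
#' direction as opposing an F1-up/F2-down feedback perturbation. The
#' incongruent group's accompanist (base voice shifted 120 mels at 325
#' degrees) sits at higher F1 / lower F2, so convergence opposes adaptation.
#'
#' The accompanist base voices are back-solved from the published session
#' averages (congruent 524/1435 mels, incongruent 641/1303 mels) minus the
#' stated shifts.
#'
#' @param group `"congruent"` or `"incongruent"`.
#' @return A list with `baseline_mean`, `baseline_sd` (length-2 numerics,
#'   mels) and `accompanist` (an `accompanist_voice`).
#' @examples
#' group_defaults("congruent")$accompanist
#' @export
group_defaults <- function(group = c("congruent", "incongruent")) {
  group <- match.arg(group)
  if (group == "congruent") {
    shift <- shift_vector(190, 100)
    avg <- c(524, 1435)
  } else {
    shift <- shift_vector(120, 325)
    avg <- c(641, 1303)
  }
  d <- shift_components(shift)
  base <- formant_pair(avg[1] - d[["dF1"]], avg[2] - d[["dF2"]], "mel")
  list(
    baseline_mean = if (group == "congruent") c(f1 = 623.89, f2 = 1368.31)
                    else c(f1 = 593.63, f2 = 1339.06),
    baseline_sd = if (group == "congruent") c(f1 = 30.10, f2 = 41.61)
                  else c(f1 = 29.98, f2 = 24.50),
    accompanist = make_accompanist(base, shift)
  )
}
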