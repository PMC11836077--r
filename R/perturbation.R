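#' Shift vector in F1-F2 mel space
#'
#' A formant shift specified in polar form: a joint magnitude (the Euclidean
#' norm of the implied `(dF1, dF2)` change) and an angle. The convention
#' throughout the package puts F1 on the abscissa and F2 on the ordinate,
#' with the angle measured counterclockwise in degrees from the +F1 axis.
#' Under this convention 315 degrees is the unique equal-component direction
#' that raises F1 and lowers F2, so a 70-mel joint shift at 315 degrees moves
#' each formant by 49.5 mels.
#'
#' @param magnitude Joint magnitude in mels, `>= 0`.
#' @param angle_deg Angle in degrees; reduced modulo 360 into `[0, 360)`.
#' @return An object of class `shift_vector`.
#' @examples
#' shift_vector(70, 315)
#' shift_components(shift_vector(70, 315))
#' @export
shift_vector <- function(magnitude, angle_deg) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1,
            is.numeric(angle_deg), length(angle_deg) == 1)
  if (!is.finite(magnitude) || magnitude < 0) {
    stop("`magnitude` must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(magnitude = magnitude, angle_deg = angle_deg %% 360),
    class = "shift_vector"
  )
}

#' @export
print.shift_vector <- function(x, ...) {
  d <- shift_components(x)
  cat(sprintf("<shift_vector> %.2f mels at %.1f deg  (dF1 = %+.2f, dF2 = %+.2f)\n",
              x$magnitude, x$angle_deg, d[["dF1"]], d[["dF2"]]))
  invisible(x)
}

#' Cartesian components of a polar formant shift
#'
#' Resolves a joint magnitude/angle shift into its per-formant components:
#' `dF1 = magnitude * cos(angle)`, `dF2 = magnitude * sin(angle)`.
#'
#' @param shift A [shift_vector()].
#' @return Named numeric vector `c(dF1, dF2)` in mels.
#' @export
shift_components <- function(shift) {
  stopifnot(inherits(shift, "shift_vector"))
  theta <- shift$angle_deg * pi / 180
  c(dF1 = shift$magnitude * cos(theta), dF2 = shift$magnitude * sin(theta))
}

#' Trial-by-trial formant perturbation schedule
#'
#' Describes the perturbation applied to a speaker's auditory feedback across
#' an experiment of blocked trials: zero through the baseline blocks, ramped
#' linearly over the first `ramp_trials` trials of `ramp_block`, held at full
#' magnitude through `hold_end_block`, and removed from `off_block` onward
#' (the after-effect phase).
#'
#' The default spec reproduces the design used for synchronous-speech
#' adaptation experiments: a 70-mel joint shift at 315 degrees (F1 up, F2
#' down by 49.5 mels each), ramped across the first 25 trials of block 3,
#' held through block 6, and switched off for block 7.
#'
#' @param shift A [shift_vector()].
#' @param ramp_block 1-based block in which the ramp starts.
#' @param ramp_trials Number of trials over which the magnitude ramps to full.
#' @param hold_end_block Last block of the hold phase.
#' @param off_block First block with the perturbation removed; must exceed
#'   `hold_end_block`.
#' @return An object of class `perturbation_spec`.
#' @examples
#' perturbation_spec()
#' magnitude_at(perturbation_spec(), block = 3, trial_in_block = 13)
#' @export
perturbation_spec <- function(shift = shift_vector(70, 315),
                              ramp_block = 3,
                              ramp_trials = 25,
                              hold_end_block = 6,
                              off_block = 7) {
  stopifnot(inherits(shift, "shift_vector"))
  for (nm in c("ramp_block", "ramp_trials", "hold_end_block", "off_block")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (hold_end_block < ramp_block) {
    stop("`hold_end_block` must be >= `ramp_block`", call. = FALSE)
  }
  if (off_block <= hold_end_block) {
    stop("`off_block` must be > `hold_end_block`", call. = FALSE)
  }
  structure(
    list(shift = shift, ramp_block = as.integer(ramp_block),
         ramp_trials = as.integer(ramp_trials),
         hold_end_block = as.integer(hold_end_block),
         off_block = as.integer(off_block)),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf(
    "<perturbation_spec> %.1f mels @ %.0f deg; ramp: block %d (first %d trials); hold through block %d; off from block %d\n",
    x$shift$magnitude, x$shift$angle_deg, x$ramp_block, x$ramp_trials,
    x$hold_end_block, x$off_block))
  invisible(x)
}

check_trial_index <- function(block, trial_in_block, n_blocks = NULL,
                              n_trials = NULL) {
  if (!is.numeric(block) || !is.numeric(trial_in_block) ||
      any(block < 1) || any(trial_in_block < 1) ||
      any(block != round(block)) || any(trial_in_block != round(trial_in_block))) {
    stop("`block` and `trial_in_block` must be positive integers (1-based)",
         call. = FALSE)
  }
  if (!is.null(n_blocks) && any(block > n_blocks)) {
    stop(sprintf("`block` outside the design (1..%d)", n_blocks), call. = FALSE)
  }
  if (!is.null(n_trials) && any(trial_in_block > n_trials)) {
    stop(sprintf("`trial_in_block` outside the design (1..%d)", n_trials),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Perturbation magnitude at a given trial
#'
#' The scheduled joint magnitude (mels) at a 1-based (block, trial) position:
#' 0 before the ramp block, `magnitude * t / ramp_trials` during the first
#' `ramp_trials` trials of the ramp block, the full magnitude through the end
#' of the hold phase, and 0 from `off_block` on.
#'
#' @param spec A [perturbation_spec()].
#' @param block,trial_in_block 1-based indices (vectorised; recycled).
#' @param n_blocks,n_trials_per_block Optional design bounds; indices beyond
#'   them raise an error.
#' @return Numeric vector of magnitudes in mels.
#' @export
magnitude_at <- function(spec, block, trial_in_block,
                         n_blocks = spec$off_block,
                         n_trials_per_block = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  check_trial_index(block, trial_in_block, n_blocks, n_trials_per_block)
  m <- spec$shift$magnitude
  out <- numeric(length(block <- as.integer(block)))
  trial <- as.integer(trial_in_block)
  if (length(trial) != length(block)) {
    n <- max(length(trial), length(block))
    block <- rep_len(block, n); trial <- rep_len(trial, n)
    out <- numeric(n)
  }
  ramping <- block == spec$ramp_block & trial <= spec$ramp_trials
  full <- (block == spec$ramp_block & trial > spec$ramp_trials) |
    (block > spec$ramp_block & block <= spec$hold_end_block)
  out[ramping] <- m * trial[ramping] / spec$ramp_trials
  out[full] <- m
  out
}

#' Perturbation vector at a given trial
#'
#' The `(dF1, dF2)` shift (mels) added to the speaker's feedback at a trial:
#' the unit direction of the spec's shift scaled by [magnitude_at()].
#'
#' @inheritParams magnitude_at
#' @return A 2-column matrix with columns `dF1`, `dF2` (one row per trial).
#' @export
perturbation_at <- function(spec, block, trial_in_block,
                            n_blocks = max(spec$off_block, block)) {
  m <- magnitude_at(spec, block, trial_in_block, n_blocks = n_blocks)
  theta <- spec$shift$angle_deg * pi / 180
  cbind(dF1 = m * cos(theta), dF2 = m * sin(theta))
}

#' Apply the scheduled perturbation to a produced formant pair
#'
#' Adds the trial's perturbation vector to a produced (mel) formant pair,
#' mimicking what the altered-feedback apparatus makes the speaker hear.
#' Identity whenever the scheduled magnitude is zero.
#'
#' @param produced A [formant_pair()] in mels (or a length-2 numeric taken to
#'   be mels).
#' @inheritParams magnitude_at
#' @return A `formant_pair` in mels.
#' @export
apply_perturbation <- function(produced, spec, block, trial_in_block) {
  p <- as_mel_pair(produced, "produced")
  d <- perturbation_at(spec, block, trial_in_block)
  formant_pair(p[1] + d[1, "dF1"], p[2] + d[1, "dF2"], unit = "mel")
}

#' Build an accompanist voice by shifting a base voice
#'
#' Accompanist stimuli are created by shifting a recorded voice's formants by
#' a fixed polar shift; the returned object records both the resulting
#' session-average formants and the shift used, so congruency between the
#' convergence direction (toward the accompanist) and the adaptation
#' direction (against the feedback perturbation) can be reasoned about.
#'
#' @param base A [formant_pair()] in mels: the unshifted voice's average.
#' @param shift A [shift_vector()] applied to it.
#' @return An object of class `accompanist_voice` with elements `formants`
#'   (a mel `formant_pair`), `base`, and `shift`.
#' @examples
#' make_accompanist(formant_pair(542.7, 1371.8), shift_vector(120, 325))
#' @export
make_accompanist <- function(base, shift) {
  stopifnot(inherits(shift, "shift_vector"))
  b <- as_mel_pair(base, "base")
  d <- shift_components(shift)
  structure(
    list(formants = formant_pair(b[1] + d[["dF1"]], b[2] + d[["dF2"]], "mel"),
         base = formant_pair(b[1], b[2], "mel"),
         shift = shift),
    class = "accompanist_voice"
  )
}

#' @export
print.accompanist_voice <- function(x, ...) {
  cat(sprintf("<accompanist_voice> F1 = %.1f, F2 = %.1f mels (base shifted by %.0f mels @ %.0f deg)\n",
              x$formants[["f1"]], x$formants[["f2"]],
              x$shift$magnitude, x$shift$angle_deg))
  invisible(x)
}

#' Phase label for a trial
#'
#' Derives the experimental phase of a (block, trial) position from the
#' perturbation schedule and the block in which synchronous speech starts.
#'
#' @inheritParams magnitude_at
#' @param sync_start_block First block with the accompanist voice present.
#' @return Character vector in `{"baseline_solo", "baseline_sync", "ramp",
#'   "hold", "after_effect"}`.
#' @export
trial_phase <- function(spec, block, trial_in_block, sync_start_block = 2) {
  check_trial_index(block, trial_in_block)
  n <- max(length(block), length(trial_in_block))
  block <- rep_len(as.integer(block), n)
  trial <- rep_len(as.integer(trial_in_block), n)
  out <- character(n)
  out[block < sync_start_block] <- "baseline_solo"
  out[block >= sync_start_block & block < spec$ramp_block] <- "baseline_sync"
  out[block == spec$ramp_block & trial <= spec$ramp_trials] <- "ramp"
  out[(block == spec$ramp_block & trial > spec$ramp_trials) |
        (block > spec$ramp_block & block <= spec$hold_end_block)] <- "hold"
  out[block >= spec$off_block] <- "after_effect"
  out
}
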