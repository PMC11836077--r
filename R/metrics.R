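#' Sentence-matched production change between two blocks
#'
#' For one participant, computes the change in produced F1/F2 from a
#' reference block to a comparison block, normalising on a
#' sentence-by-sentence basis: each sentence's formants in the comparison
#' block are differenced against the same sentence's formants in the
#' reference block, and the per-sentence differences are averaged. Sentence
#' matching removes stable per-sentence differences in vowel content from
#' the change measure. Sentences missing from either block are skipped and
#' counted. If a sentence appears more than once within a block its values
#' are averaged first.
#'
#' @param trials Trial table with columns `participant_id`, `block`,
#'   `sentence_id`, `f1_mel`, `f2_mel` (as produced by [simulate_cohort()]
#'   or read from CSV).
#' @param participant Participant identifier to subset on.
#' @param ref_block,cmp_block 1-based block numbers.
#' @return An object of class `production_change`: a list with `dF1`, `dF2`
#'   (mels, means over matched sentences), `per_sentence` (data.frame of
#'   per-sentence differences), and `n_skipped`.
#' @export
production_change <- function(trials, participant, ref_block, cmp_block) {
  d <- trials[trials$participant_id == participant, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("participant '%s' not in table", participant),
                     call. = FALSE)
  ref <- d[d$block == ref_block, , drop = FALSE]
  cmp <- d[d$block == cmp_block, , drop = FALSE]
  if (!nrow(ref) || !nrow(cmp)) {
    stop(sprintf("blocks %s and %s must both be present for participant '%s'",
                 ref_block, cmp_block, participant), call. = FALSE)
  }
  ref_f1 <- tapply(ref$f1_mel, ref$sentence_id, mean)
  ref_f2 <- tapply(ref$f2_mel, ref$sentence_id, mean)
  cmp_f1 <- tapply(cmp$f1_mel, cmp$sentence_id, mean)
  cmp_f2 <- tapply(cmp$f2_mel, cmp$sentence_id, mean)
  common <- intersect(names(ref_f1), names(cmp_f1))
  n_skipped <- length(union(names(ref_f1), names(cmp_f1))) - length(common)
  if (!length(common)) {
    stop("no overlapping sentences between the two blocks", call. = FALSE)
  }
  per_sentence <- data.frame(
    sentence_id = common,
    dF1 = unname(cmp_f1[common] - ref_f1[common]),
    dF2 = unname(cmp_f2[common] - ref_f2[common]),
    stringsAsFactors = FALSE
  )
  structure(
    list(participant_id = participant,
         ref_block = ref_block, cmp_block = cmp_block,
         dF1 = mean(per_sentence$dF1), dF2 = mean(per_sentence$dF2),
         per_sentence = per_sentence, n_skipped = n_skipped),
    class = "production_change"
  )
}

#' @export
print.production_change <- function(x, ...) {
  cat(sprintf("<production_change> %s: block %s -> %s: dF1 = %+.2f, dF2 = %+.2f mels (%d sentences, %d skipped)\n",
              x$participant_id, x$ref_block, x$cmp_block, x$dF1, x$dF2,
              nrow(x$per_sentence), x$n_skipped))
  invisible(x)
}

#' Signed adaptation projection of a formant-change vector
#'
#' The adaptation statistic: the component of a production-change vector
#' `(dF1, dF2)` along the direction of perfect adaptation, i.e., along the
#' inverse of the perturbation vector. Geometrically this is the magnitude
#' of the change vector times the cosine of the angle between it and the
#' inverse perturbation — equivalently, its scalar product with the unit
#' vector along `-p`. Positive values are formant changes opposing the
#' perturbation (adaptation); negative values follow it (a "following"
#' response). A zero change vector scores 0 (the angle is undefined there;
#' the dot-product form makes 0 the natural limit). The score is bounded in
#' magnitude by the change vector's norm, with equality iff the change is
#' collinear with the perturbation.
#'
#' @param dF1,dF2 Production change in mels (vectorised).
#' @param spec A [perturbation_spec()] (or a [shift_vector()]) with nonzero
#'   magnitude, giving the perturbation direction.
#' @return Numeric vector of signed adaptation scores in mels.
#' @examples
#' spec <- perturbation_spec()
#' adaptation_projection(-49.5, 49.5, spec)   # perfect opposition: +70
#' adaptation_projection(49.5, -49.5, spec)   # pure following: -70
#' @export
adaptation_projection <- function(dF1, dF2, spec) {
  shift <- if (inherits(spec, "perturbation_spec")) spec$shift else spec
  stopifnot(inherits(shift, "shift_vector"))
  if (shift$magnitude <= 0) {
    stop("perturbation magnitude must be nonzero to define the adaptation direction",
         call. = FALSE)
  }
  theta <- shift$angle_deg * pi / 180
  # unit vector along the inverse perturbation
  -(dF1 * cos(theta) + dF2 * sin(theta))
}

#' Per-trial adaptation scores relative to a baseline block
#'
#' For one participant, differences every trial's F1/F2 against the same
#' sentence's value in the reference block and projects the change onto the
#' direction of perfect adaptation ([adaptation_projection()]). Trials whose
#' sentence is missing from the reference block are skipped (attribute
#' `n_skipped`).
#'
#' @inheritParams production_change
#' @param spec A [perturbation_spec()].
#' @param ref_block Baseline block whose per-sentence values anchor the
#'   change vectors.
#' @param blocks Blocks to score; defaults to all blocks after the baseline.
#' @return Data.frame `block`, `trial_in_block`, `sentence_id`, `score`
#'   (mels), with attribute `n_skipped`.
#' @export
trial_adaptation <- function(trials, participant, spec, ref_block = 2,
                             blocks = NULL) {
  d <- trials[trials$participant_id == participant, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("participant '%s' not in table", participant),
                     call. = FALSE)
  ref <- d[d$block == ref_block, , drop = FALSE]
  if (!nrow(ref)) stop(sprintf("baseline block %s missing for participant '%s'",
                               ref_block, participant), call. = FALSE)
  if (is.null(blocks)) {
    blocks <- setdiff(sort(unique(d$block)), seq_len(ref_block))
  }
  ref_f1 <- tapply(ref$f1_mel, ref$sentence_id, mean)
  ref_f2 <- tapply(ref$f2_mel, ref$sentence_id, mean)
  cmp <- d[d$block %in% blocks, , drop = FALSE]
  idx <- match(as.character(cmp$sentence_id), names(ref_f1))
  skipped <- is.na(idx)
  cmp <- cmp[!skipped, , drop = FALSE]
  idx <- idx[!skipped]
  out <- data.frame(
    block = cmp$block,
    trial_in_block = cmp$trial_in_block,
    sentence_id = cmp$sentence_id,
    score = adaptation_projection(cmp$f1_mel - unname(ref_f1[idx]),
                                  cmp$f2_mel - unname(ref_f2[idx]),
                                  spec),
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Block-averaged adaptation scores
#'
#' Averages [trial_adaptation()] scores within each block following the
#' introduction of the perturbation (ramp block through the final block),
#' all measured against the sentence-matched baseline block.
#'
#' @inheritParams trial_adaptation
#' @return Data.frame `block`, `adaptation` (mean score, mels), `n_trials`;
#'   attribute `n_skipped` carries the count of unmatched trials.
#' @export
blockwise_adaptation <- function(trials, participant, spec, ref_block = 2) {
  d <- trials[trials$participant_id == participant, , drop = FALSE]
  blocks <- sort(unique(d$block))
  blocks <- blocks[blocks >= spec$ramp_block]
  scores <- trial_adaptation(trials, participant, spec, ref_block, blocks)
  agg <- tapply(scores$score, factor(scores$block, levels = blocks), mean)
  n <- tapply(scores$score, factor(scores$block, levels = blocks), length)
  out <- data.frame(block = blocks,
                    adaptation = unname(as.numeric(agg)),
                    n_trials = unname(as.integer(n)))
  attr(out, "n_skipped") <- attr(scores, "n_skipped")
  out
}

#' Convergence-related formant change across the baseline blocks
#'
#' The change in produced F1/F2 from the solo-speech baseline block to the
#' first synchronous block (before any perturbation), sentence-matched.
#' Movement toward the accompanist voice in this window is the signature of
#' vocal convergence.
#'
#' @inheritParams production_change
#' @param solo_block,sync_block Blocks to contrast (defaults 1 and 2).
#' @return Named numeric `c(dF1, dF2)` in mels.
#' @export
convergence_change <- function(trials, participant, solo_block = 1,
                               sync_block = 2) {
  pc <- production_change(trials, participant, solo_block, sync_block)
  c(dF1 = pc$dF1, dF2 = pc$dF2)
}

#' Adaptation-convergence congruency score
#'
#' Quantifies how far a participant's formant change across the baseline
#' blocks (solo to synchronous, i.e., the convergence window) agrees with
#' the direction of perfect adaptation to the subsequent perturbation: the
#' [adaptation_projection()] of the baseline-window change vector. Positive
#' scores mean the convergence-driven change already pointed against the
#' upcoming perturbation.
#'
#' @inheritParams adaptation_projection
#' @return Signed score in mels.
#' @examples
#' congruency_score(-7.55, 10.51, perturbation_spec())
#' @export
congruency_score <- function(dF1, dF2, spec) {
  adaptation_projection(dF1, dF2, spec)
}

#' Baseline-vs-accompanist eligibility screen
#'
#' A participant's baseline must sit on the intended side of their
#' accompanist's formants for the congruency manipulation to act as
#' designed: in the congruent group, baseline F1 above and F2 below the
#' accompanist (so convergence lowers F1 and raises F2, the adaptation
#' direction); in the incongruent group the reverse. Ties are ineligible.
#'
#' @param baseline,accompanist Length-2 numerics or [formant_pair()]s in the
#'   same unit (mels).
#' @param group `"congruent"` or `"incongruent"`.
#' @return Logical scalar.
#' @export
screen_participant <- function(baseline, accompanist,
                               group = c("congruent", "incongruent")) {
  group <- match.arg(group)
  if (inherits(baseline, "formant_pair") &&
      inherits(accompanist, "formant_pair") &&
      formant_unit(baseline) != formant_unit(accompanist)) {
    stop("baseline and accompanist must share a unit", call. = FALSE)
  }
  b <- unname(as.numeric(baseline))
  a <- unname(as.numeric(accompanist))
  if (group == "congruent") b[1] > a[1] && b[2] < a[2]
  else b[1] < a[1] && b[2] > a[2]
}

#' Componentwise distance between baseline and accompanist formants
#'
#' Absolute F1 and F2 differences between a baseline and an accompanist
#' formant pair (mels) — the acoustic distance a full convergence response
#' would have to cover.
#'
#' @inheritParams screen_participant
#' @return Named numeric `c(dF1, dF2)` of absolute differences in mels.
#' @export
accompanist_distance <- function(baseline, accompanist) {
  b <- unname(as.numeric(baseline))
  a <- unname(as.numeric(accompanist))
  c(dF1 = abs(b[1] - a[1]), dF2 = abs(b[2] - a[2]))
}
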