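#' One-sample t-test
#'
#' Computed from first principles: `t = (mean(x) - mu0) / (sd(x)/sqrt(n))`
#' with `n - 1` degrees of freedom; p-values from the t distribution.
#'
#' @param x Numeric sample, `n >= 2` with nonzero variance.
#' @param mu0 Null mean.
#' @param sidedness `"two"`, `"greater"`, or `"less"`.
#' @return An object of class `t_result`: list with `statistic`, `df`, `p`,
#'   `estimate` (sample mean), `sidedness`.
#' @export
one_sample_t <- function(x, mu0 = 0, sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  n <- length(x)
  tval <- (mean(x) - mu0) / (s / sqrt(n))
  t_result(tval, n - 1, sidedness, estimate = mean(x))
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom, computed from first principles.
#'
#' @param x,y Numeric samples, each `n >= 2`.
#' @inheritParams one_sample_t
#' @return A `t_result` (estimate is `mean(x) - mean(y)`).
#' @export
welch_t <- function(x, y, sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 observations per sample", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  if (vx == 0 && vy == 0) stop("zero variance in both samples", call. = FALSE)
  se2x <- vx / nx; se2y <- vy / ny
  tval <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  t_result(tval, df, sidedness, estimate = mean(x) - mean(y))
}

t_result <- function(statistic, df, sidedness, estimate) {
  p <- switch(sidedness,
              two = 2 * stats::pt(-abs(statistic), df),
              greater = stats::pt(statistic, df, lower.tail = FALSE),
              less = stats::pt(statistic, df))
  structure(list(statistic = statistic, df = df, p = p,
                 estimate = estimate, sidedness = sidedness),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.4g, p = %.4g (%s-sided), estimate = %.4g\n",
              x$df, x$statistic, x$p, x$sidedness, x$estimate))
  invisible(x)
}

#' Classify a participant as adapter, follower, or neither
#'
#' A two-sided one-sample t-test of the participant's per-trial adaptation
#' scores against zero: `"adapter"` if the mean is significantly above zero
#' (formant changes oppose the perturbation), `"follower"` if significantly
#' below (changes follow it), `"none"` otherwise. By convention the scores
#' are the final hold block's per-trial values ([trial_adaptation()]
#' restricted to that block).
#'
#' @param scores Numeric vector of per-trial adaptation scores (mels).
#' @param alpha Significance level for the two-sided test.
#' @param participant_id Optional identifier carried into the result.
#' @return An object of class `participant_classification`: list with
#'   `participant_id`, `label`, and `test` (a `t_result`).
#' @export
classify_participant <- function(scores, alpha = 0.05, participant_id = NA) {
  tt <- one_sample_t(scores, mu0 = 0, sidedness = "two")
  label <- if (tt$p < alpha && tt$estimate > 0) "adapter"
           else if (tt$p < alpha && tt$estimate < 0) "follower"
           else "none"
  structure(list(participant_id = participant_id, label = label, test = tt),
            class = "participant_classification")
}

#' @export
print.participant_classification <- function(x, ...) {
  cat(sprintf("<%s> %s: ", "participant_classification", x$participant_id))
  cat(x$label, "-- "); print(x$test)
  invisible(x)
}

#' Classify every participant in a trial table
#'
#' Runs [classify_participant()] on each participant's per-trial adaptation
#' scores from the final hold block (sentence-matched against the baseline
#' block) and tabulates adapter/follower/none counts per group.
#'
#' @inheritParams blockwise_adaptation
#' @param block Block whose per-trial scores are tested (default: the
#'   schedule's final hold block).
#' @param alpha Significance level.
#' @return A list with `classifications` (data.frame: `participant_id`,
#'   `group`, `label`, `t`, `df`, `p`, `mean_score`) and `counts` (group x
#'   label table including all three labels).
#' @export
classify_cohort <- function(trials, spec, block = spec$hold_end_block,
                            ref_block = 2, alpha = 0.05) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    sc <- trial_adaptation(trials, id, spec, ref_block, blocks = block)
    cl <- classify_participant(sc$score, alpha, id)
    data.frame(participant_id = id,
               group = trials$group[match(id, trials$participant_id)],
               label = cl$label,
               t = cl$test$statistic, df = cl$test$df, p = cl$test$p,
               mean_score = cl$test$estimate,
               stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, rows)
  counts <- table(factor(cls$group, levels = unique(cls$group)),
                  factor(cls$label, levels = c("adapter", "follower", "none")))
  list(classifications = cls, counts = counts)
}

#' Group contrast on block-wise adaptation via a linear mixed model
#'
#' Fits a linear mixed model to per-trial adaptation scores with fixed
#' effects for block, group, and their interaction, and random intercepts
#' for participant and sentence, delegating the fit to `lmerTest`/`lme4`.
#' The block-by-group interaction — whether adaptation builds up differently
#' across blocks in the two groups — is tested with a likelihood-ratio test
#' against the no-interaction model. If the full random structure is
#' singular, the sentence intercept is dropped with a warning and the
#' simplification is recorded in the result.
#'
#' @param scores Long data.frame with columns `score`, `block`, `group`,
#'   `participant_id`, `sentence_id` (e.g., stacked [trial_adaptation()]
#'   output; see [cohort_adaptation_scores()]).
#' @param formula Model formula; the default treats block as a numeric
#'   trend. Override to change the fixed or random structure.
#' @return A list with `fit` (the `lmerModLmerTest` object), `coefficients`
#'   (fixed-effect table with Satterthwaite tests), `interaction`
#'   (data.frame with the LRT chi-square, df, and p for block:group), and
#'   `simplified` (logical: random structure reduced).
#' @export
group_contrast_lmm <- function(scores,
                               formula = score ~ block * group +
                                 (1 | participant_id) + (1 | sentence_id)) {
  stopifnot(all(c("score", "block", "group", "participant_id") %in%
                  names(scores)))
  scores$group <- factor(scores$group)
  simplified <- FALSE
  fit <- suppressMessages(lmerTest::lmer(formula, data = scores, REML = FALSE))
  if (lme4::isSingular(fit, tol = 1e-4) &&
      "sentence_id" %in% names(lme4::ranef(fit))) {
    warning("singular fit with sentence intercepts; refitting without them",
            call. = FALSE)
    simplified <- TRUE
    formula <- stats::update(formula, . ~ . - (1 | sentence_id))
    fit <- suppressMessages(lmerTest::lmer(formula, data = scores,
                                           REML = FALSE))
  }
  reduced <- suppressMessages(stats::update(fit, . ~ . - block:group))
  lrt <- stats::anova(reduced, fit)
  list(fit = fit,
       coefficients = stats::coef(summary(fit)),
       interaction = data.frame(chisq = lrt$Chisq[2],
                                df = lrt$Df[2],
                                p = lrt$`Pr(>Chisq)`[2]),
       simplified = simplified)
}

#' Stack per-trial adaptation scores for a whole cohort
#'
#' Convenience wrapper producing the long table [group_contrast_lmm()]
#' expects: per-trial sentence-matched adaptation scores for every
#' participant, for the blocks after the baseline.
#'
#' @inheritParams classify_cohort
#' @param blocks Blocks to include (default: ramp block through final block).
#' @return Data.frame `participant_id`, `group`, `block`, `trial_in_block`,
#'   `sentence_id`, `score`.
#' @export
cohort_adaptation_scores <- function(trials, spec, ref_block = 2,
                                     blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- seq(spec$ramp_block, max(trials$block))
  }
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    sc <- trial_adaptation(trials, id, spec, ref_block, blocks)
    sc$participant_id <- id
    sc$group <- trials$group[match(id, trials$participant_id)]
    sc
  })
  do.call(rbind, out)[, c("participant_id", "group", "block",
                          "trial_in_block", "sentence_id", "score")]
}
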