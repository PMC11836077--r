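#' Participant profile for the cohort simulator
#'
#' Parameters of the generative model used to simulate one participant:
#' a baseline formant pair `B`, a convergence drive that moves the auditory
#' target toward the accompanist, and a single-state error-correction
#' process that counters perceived deviation of the (perturbed) feedback
#' from the target.
#'
#' The dynamics are, per trial `t` (vector quantities in F1-F2 mel space):
#' target `T_t = B + gamma_t * (A - B)` with
#' `gamma_t = conv_asymptote * (1 - exp(-t_sync / conv_rate))` once
#' synchronous speech has begun (0 before); production
#' `f_t = B + x_t + s_j + eps_t` with per-sentence effect `s_j` and trial
#' noise `eps_t`; perceived error `e_t = (f_t + p_t) - T_t` with `p_t` the
#' scheduled perturbation; and state update
#' `x_{t+1} = retention * x_t - learning_rate * e_t`, `x_1 = 0`.
#'
#' This model is a deliberately minimal stand-in embodying the
#' target-updating account of vocal convergence (convergence shifts the
#' targets that sensorimotor error correction then works against); it is a
#' simulation device for pipeline validation, not a fitted cognitive model.
#'
#' @param id Participant identifier (character).
#' @param group `"congruent"` or `"incongruent"`.
#' @param baseline Length-2 numeric or [formant_pair()] in mels.
#' @param conv_asymptote Asymptotic convergence fraction `gamma_inf` in
#'   `[0, 1]`: 0 = no convergence, 1 = target moves fully onto the
#'   accompanist.
#' @param conv_rate Convergence time constant in synchronous trials (> 0).
#' @param retention State retention factor `a` in `(0, 1]`.
#' @param learning_rate Error-correction gain `b` in `[0, 1)`.
#' @param trial_noise_sd Per-trial production noise SD (mels, per formant).
#' @param sentence_effect_sd SD of per-sentence formant offsets (mels),
#'   shared across blocks within a participant.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(id, group = c("congruent", "incongruent"),
                                baseline,
                                conv_asymptote = 0.4,
                                conv_rate = 20,
                                retention = 0.99,
                                learning_rate = 0.08,
                                trial_noise_sd = 8,
                                sentence_effect_sd = 10) {
  group <- match.arg(group)
  b <- as_mel_pair(baseline, "baseline")
  stopifnot(conv_asymptote >= 0, conv_asymptote <= 1, conv_rate > 0,
            retention > 0, retention <= 1,
            learning_rate >= 0, learning_rate < 1,
            trial_noise_sd >= 0, sentence_effect_sd >= 0)
  if (1 - retention + learning_rate <= 0 ||
      abs(retention - learning_rate) >= 1) {
    stop("unstable dynamics: require 1 - retention + learning_rate > 0 and |retention - learning_rate| < 1",
         call. = FALSE)
  }
  structure(
    list(id = as.character(id), group = group,
         baseline = c(f1 = b[1], f2 = b[2]),
         conv_asymptote = conv_asymptote, conv_rate = conv_rate,
         retention = retention, learning_rate = learning_rate,
         trial_noise_sd = trial_noise_sd,
         sentence_effect_sd = sentence_effect_sd),
    class = "participant_profile"
  )
}

#' Draw an eligible participant for a group
#'
#' Samples a baseline formant pair from the group's bivariate normal
#' (independent F1/F2, means and SDs from [group_defaults()]) and redraws
#' until the baseline relates to the group's accompanist as the design
#' intends (see [screen_participant()]) — emulating the screening that
#' excludes participants whose baseline sits on the wrong side of the
#' accompanist voice.
#'
#' @param group `"congruent"` or `"incongruent"`.
#' @param design An [experiment_design()] (unused by the default sampler but
#'   accepted for custom baselines tied to a design).
#' @param id Identifier for the new profile.
#' @param seed Optional integer seed for reproducible draws.
#' @param baseline_mean,baseline_sd Override the group's baseline
#'   distribution (length-2, mels).
#' @param accompanist Override the group's `accompanist_voice`.
#' @param ... Dynamics parameters passed to [participant_profile()].
#' @param max_redraws Redraw limit; exceeding it signals a mis-specified
#'   configuration (e.g., a baseline distribution on the wrong side of the
#'   accompanist).
#' @return A [participant_profile()] whose baseline passes screening.
#' @export
sample_participant <- function(group = c("congruent", "incongruent"),
                               design = experiment_design(),
                               id = group, seed = NULL,
                               baseline_mean = NULL, baseline_sd = NULL,
                               accompanist = NULL, ...,
                               max_redraws = 1000) {
  group <- match.arg(group)
  defs <- group_defaults(group)
  if (is.null(baseline_mean)) baseline_mean <- defs$baseline_mean
  if (is.null(baseline_sd)) baseline_sd <- defs$baseline_sd
  if (is.null(accompanist)) accompanist <- defs$accompanist
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_redraws)) {
    b <- stats::rnorm(2, mean = baseline_mean, sd = baseline_sd)
    if (b[1] > 0 && b[2] > b[1] &&
        screen_participant(b, accompanist$formants, group)) {
      return(participant_profile(id = id, group = group, baseline = b, ...))
    }
  }
  stop(sprintf("no eligible baseline drawn for group '%s' in %d attempts; check the baseline/accompanist configuration",
               group, max_redraws), call. = FALSE)
}

# Per-trial convergence fraction gamma_t for global trial indices 1..n.
convergence_fraction <- function(profile, design, trial) {
  first_sync <- (design$sync_start_block - 1L) * design$n_sentences + 1L
  t_sync <- pmax(0L, trial - first_sync + 1L)
  ifelse(t_sync > 0,
         profile$conv_asymptote * (1 - exp(-t_sync / profile$conv_rate)),
         0)
}

#' Simulate one participant's trial sequence
#'
#' Runs the generative model in [participant_profile()] across the full
#' design, emitting one record per produced sentence with the sentence order
#' randomised within each block.
#'
#' @param profile A [participant_profile()].
#' @param design An [experiment_design()].
#' @param accompanist An `accompanist_voice` (defaults to the profile
#'   group's).
#' @param seed Optional integer seed.
#' @return A data.frame with one row per trial: `participant_id`, `group`,
#'   `block`, `trial_in_block`, `sentence_id`, `f1_mel`, `f2_mel`, `phase`,
#'   plus ground-truth columns `target_f1_mel`, `target_f2_mel`,
#'   `state_f1_mel`, `state_f2_mel`, `gamma`.
#' @export
simulate_participant <- function(profile, design = experiment_design(),
                                 accompanist = NULL, seed = NULL) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(design, "experiment_design"))
  if (is.null(accompanist)) accompanist <- group_defaults(profile$group)$accompanist
  if (!is.null(seed)) set.seed(seed)

  ns <- design$n_sentences
  nb <- design$n_blocks
  n <- ns * nb
  A <- as_mel_pair(accompanist$formants, "accompanist")
  B <- unname(profile$baseline)
  a <- profile$retention
  bgain <- profile$learning_rate

  sentence <- as.vector(vapply(seq_len(nb), function(i) sample.int(ns),
                               integer(ns)))
  s_eff <- matrix(stats::rnorm(2 * ns, sd = profile$sentence_effect_sd),
                  nrow = ns, ncol = 2)
  eps <- matrix(stats::rnorm(2 * n, sd = profile$trial_noise_sd),
                nrow = n, ncol = 2)

  block <- rep(seq_len(nb), each = ns)
  trial_in_block <- rep(seq_len(ns), times = nb)
  gamma <- convergence_fraction(profile, design, seq_len(n))
  pert <- perturbation_at(design$perturbation, block, trial_in_block)

  x <- matrix(0, nrow = n, ncol = 2)
  f <- matrix(0, nrow = n, ncol = 2)
  tgt <- matrix(0, nrow = n, ncol = 2)
  xt <- c(0, 0)
  for (t in seq_len(n)) {
    tgt[t, ] <- B + gamma[t] * (A - B)
    x[t, ] <- xt
    f[t, ] <- B + xt + s_eff[sentence[t], ] + eps[t, ]
    err <- (f[t, ] + pert[t, ]) - tgt[t, ]
    xt <- a * xt - bgain * err
  }

  data.frame(
    participant_id = profile$id,
    group = profile$group,
    block = block,
    trial_in_block = trial_in_block,
    sentence_id = sentence,
    f1_mel = f[, 1], f2_mel = f[, 2],
    phase = trial_phase(design$perturbation, block, trial_in_block,
                        design$sync_start_block),
    target_f1_mel = tgt[, 1], target_f2_mel = tgt[, 2],
    state_f1_mel = x[, 1], state_f2_mel = x[, 2],
    gamma = gamma,
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-group cohort
#'
#' Draws eligible participants for both groups ([sample_participant()]) and
#' simulates each ([simulate_participant()]). One master seed fans out into
#' independent per-participant streams, so cohorts are reproducible and
#' participants mutually independent.
#'
#' @param design An [experiment_design()].
#' @param master_seed Integer master seed.
#' @param profile_args Named list of dynamics parameters forwarded to every
#'   [participant_profile()] (e.g., `list(conv_asymptote = 0.9)`).
#' @return A list with `trials` (the observable table: identity, `f1_mel`,
#'   `f2_mel`, `phase`), `truth` (hidden per-trial targets, states, and
#'   convergence fractions), and `profiles` (the sampled
#'   `participant_profile`s).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(master_seed = 1)
#' table(cohort$trials$group) / 350
#' }
#' @export
simulate_cohort <- function(design = experiment_design(), master_seed = 1,
                            profile_args = list()) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(master_seed)
  groups <- c(rep("congruent", design$n_congruent),
              rep("incongruent", design$n_incongruent))
  ids <- c(sprintf("C%02d", seq_len(design$n_congruent)),
           sprintf("I%02d", seq_len(design$n_incongruent)))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * length(groups))
  sample_seeds <- seeds[seq_along(groups)]
  sim_seeds <- seeds[length(groups) + seq_along(groups)]

  profiles <- vector("list", length(groups))
  tabs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    profiles[[i]] <- do.call(sample_participant, c(
      list(group = groups[i], design = design, id = ids[i],
           seed = sample_seeds[i]),
      profile_args))
    tabs[[i]] <- simulate_participant(profiles[[i]], design,
                                      seed = sim_seeds[i])
  }
  full <- do.call(rbind, tabs)
  truth_cols <- c("participant_id", "block", "trial_in_block",
                  "target_f1_mel", "target_f2_mel",
                  "state_f1_mel", "state_f2_mel", "gamma")
  obs_cols <- c("participant_id", "group", "block", "trial_in_block",
                "sentence_id", "f1_mel", "f2_mel", "phase")
  names(profiles) <- ids
  list(trials = full[, obs_cols],
       truth = full[, truth_cols],
       profiles = profiles)
}

#' Closed-form noiseless adaptation prediction
#'
#' Evaluates the expected (noise-free) state trajectory of the generative
#' model as a linear filter — `x_t = b * sum_{k<t} (a-b)^(t-1-k) d_k` with
#' drive `d_k = gamma_k (A - B) - p_k` — without running the stochastic
#' simulator, and projects block-mean state changes relative to the baseline
#' block onto the direction of perfect adaptation. Because the dynamics are
#' linear and the noise terms have zero mean, this is exactly the expected
#' value of the simulator's block-wise adaptation statistic; it serves as an
#' independent oracle for parameter-recovery checks.
#'
#' @param profile A [participant_profile()].
#' @param design An [experiment_design()].
#' @param accompanist An `accompanist_voice` (defaults to the group's).
#' @param ref_block Baseline block for the adaptation contrast.
#' @return A list with `state` (n x 2 matrix of expected states), `gamma`,
#'   and `block_adaptation` (named numeric: expected adaptation score per
#'   block from the ramp block through the final block).
#' @export
analytic_adaptation <- function(profile, design = experiment_design(),
                                accompanist = NULL, ref_block = 2) {
  stopifnot(inherits(profile, "participant_profile"))
  if (is.null(accompanist)) accompanist <- group_defaults(profile$group)$accompanist
  ns <- design$n_sentences
  n <- ns * design$n_blocks
  A <- as_mel_pair(accompanist$formants, "accompanist")
  B <- unname(profile$baseline)
  block <- rep(seq_len(design$n_blocks), each = ns)
  trial_in_block <- rep(seq_len(ns), times = design$n_blocks)
  gamma <- convergence_fraction(profile, design, seq_len(n))
  pert <- perturbation_at(design$perturbation, block, trial_in_block)
  drive <- cbind(gamma * (A[1] - B[1]) - pert[, "dF1"],
                 gamma * (A[2] - B[2]) - pert[, "dF2"])
  pole <- profile$retention - profile$learning_rate
  # x_{t+1} = pole * x_t + b * d_t, x_1 = 0  =>  recursive filter, lagged once
  xf <- apply(profile$learning_rate * drive, 2, function(col) {
    as.numeric(stats::filter(col, pole, method = "recursive"))
  })
  x <- rbind(c(0, 0), xf[-n, , drop = FALSE])

  ref_idx <- block == ref_block
  blocks_out <- seq(design$perturbation$ramp_block, design$n_blocks)
  ba <- vapply(blocks_out, function(b) {
    d <- colMeans(x[block == b, , drop = FALSE]) - colMeans(x[ref_idx, , drop = FALSE])
    adaptation_projection(d[1], d[2], design$perturbation)
  }, numeric(1))
  names(ba) <- blocks_out
  list(state = x, gamma = gamma, block_adaptation = ba)
}
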