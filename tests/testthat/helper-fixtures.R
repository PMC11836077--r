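# Shared fixtures and independent oracles.

default_spec <- function() perturbation_spec()

# Angle-based brute-force projection: explicit angular difference between the
# change vector and the inverse perturbation, cosine times magnitude, sign
# from the orientation of the cross product. Independent of the dot-product
# implementation in the package.
brute_force_projection <- function(dF1, dF2, spec) {
  shift <- if (inherits(spec, "perturbation_spec")) spec$shift else spec
  mag <- sqrt(dF1^2 + dF2^2)
  if (mag == 0) return(0)
  inv <- -c(cos(shift$angle_deg * pi / 180), sin(shift$angle_deg * pi / 180))
  v <- c(dF1, dF2) / mag
  cosang <- max(-1, min(1, sum(v * inv)))
  mag * cos(acos(cosang))
}

# Build a trial table for one participant from a per-block data.frame of
# sentence formants plus per-block offsets: offsets is a list mapping block
# number to c(dF1, dF2) added to the base sentence values.
make_trials <- function(base, offsets, participant = "p1",
                        group = "congruent") {
  blocks <- as.integer(names(offsets))
  do.call(rbind, lapply(blocks, function(b) {
    off <- offsets[[as.character(b)]]
    data.frame(participant_id = participant, group = group, block = b,
               trial_in_block = seq_len(nrow(base)),
               sentence_id = base$sentence_id,
               f1_mel = base$f1 + off[1], f2_mel = base$f2 + off[2],
               phase = "hold", stringsAsFactors = FALSE)
  }))
}

base_sentences <- function(n = 4) {
  data.frame(sentence_id = seq_len(n),
             f1 = 600 + 5 * seq_len(n),
             f2 = 1400 - 7 * seq_len(n))
}

# A small noiseless design for dynamics checks.
quiet_profile <- function(group = "congruent", baseline = c(600, 1400), ...) {
  participant_profile("q", group, baseline, trial_noise_sd = 0,
                      sentence_effect_sd = 0, ...)
}
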