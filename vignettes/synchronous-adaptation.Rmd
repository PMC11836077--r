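---
title: "Measuring speech motor adaptation under concurrent vocal convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring speech motor adaptation under concurrent vocal convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncadapt)
```

## The paradigm and its geometry

A speaker reads 50 sentences once per block across 7 blocks while hearing
their own voice through headphones. Block 1 is solo speech; from block 2 a
pre-recorded accompanist voice is added and the speaker reads in synchrony
with it. From block 3 the speaker's feedback formants are perturbed: the
shift ramps linearly across the first 25 trials of block 3, is held at full
magnitude through block 6, and is removed for block 7 (after-effects).

All geometry lives in F1–F2 mel space (`hz_to_mel()` uses
`2595·log10(1 + f/700)`), with F1 on the abscissa, F2 on the ordinate, and
angles counterclockwise from the +F1 axis. A shift is specified in polar
form by its joint magnitude and angle; the default self-feedback
perturbation, 70 mels at 315°, splits into +49.5 mels on F1 and −49.5 mels
on F2 — F1 up, F2 down. This axis convention is the unique one consistent
with all three shift patterns the design uses: 70@315° (F1 up, F2 down,
equal components), 120@325° (F1 up, F2 down) and 190@100° (F1 down, F2 up).

```{r geometry}
shift_components(shift_vector(70, 315))
magnitude_at(perturbation_spec(), block = 3, trial_in_block = c(1, 13, 25, 26))
```

Two accompanist voices create the congruency manipulation. Both are stored
as session-average formant pairs; their bases are back-solved from the
published averages (congruent 524/1435 mels, incongruent 641/1303 mels).
Converging toward the congruent voice (lower F1, higher F2 than the
speakers' baselines) moves formants in the same direction as opposing the
perturbation; converging toward the incongruent voice moves them along it.

## The adaptation statistic

For one participant, the production change from the block-2 baseline to a
later trial is computed sentence-by-sentence: each trial's F1/F2 minus the
same sentence's block-2 value. Sentence matching removes stable
per-sentence differences in vowel content, which would otherwise dwarf the
tens-of-mels effects of interest. The change vector **d** = (ΔF1, ΔF2) is
then projected onto the direction of perfect adaptation — the inverse of
the perturbation vector **p**:

$$A = \lVert d \rVert \cos \angle(d, -p) \;=\; d \cdot \frac{-p}{\lVert p \rVert}.$$

The two forms are identical; the package computes the dot product and the
test suite checks it against an explicit angle-based implementation. The
statistic is linear in **d** (so the group mean of projections equals the
projection of the group-mean change), bounded by `|d|`, and signed:
positive scores oppose the perturbation, negative scores follow it. A zero
change vector scores 0 — the angle is undefined there and the dot product
supplies the natural limit. Per-trial scores are averaged within blocks 3–7
(`blockwise_adaptation()`); the same projection applied to the block-1 to
block-2 change (the convergence window, before any perturbation) gives the
adaptation–convergence congruency score.

Trials whose sentence is missing from the baseline block are skipped and
counted, never imputed; the per-trial baseline matching is applied uniformly
to blocks 3–7.

## The generative model behind the simulator

The simulator is a deliberately minimal stand-in embodying the
target-updating account of convergence: hearing the accompanist shifts the
auditory targets that sensorimotor error correction then works against. It
is a device for validating the pipeline with known ground truth, not a
fitted cognitive model, and the package makes no claim that it is the true
mechanism (reflexive mimicry summed with compensation would produce similar
observable tables).

Per trial $t$, with baseline $B$, accompanist $A$ and state $x_t$ (all
2-vectors in mels):

- target: $T_t = B + \gamma_t (A - B)$, with convergence fraction
  $\gamma_t = \gamma_\infty (1 - e^{-t_s/\tau_c})$ over synchronous trials
  $t_s$ (0 before block 2);
- production: $f_t = B + x_t + s_j + \varepsilon_t$, with a per-sentence
  offset $s_j$ (drawn once per participant, shared across blocks — exactly
  the structure sentence-matched normalisation removes) and trial noise
  $\varepsilon_t$;
- perceived error: $e_t = (f_t + p_t) - T_t$, where $p_t$ is the scheduled
  perturbation;
- state update: $x_{t+1} = a\,x_t - b\,e_t$, $x_1 = 0$.

Defaults: retention $a = 0.99$, correction gain $b = 0.08$, trial noise
$\sigma = 8$ mels, sentence-effect SD $\sigma_s = 10$ mels,
$\tau_c = 20$ synchronous trials, $\gamma_\infty = 0.4$ for both groups.
These place simulated block-6 group means in the tens-of-mels range typical
of sentence-level formant adaptation, with the congruent group above the
incongruent group. Baselines are drawn per group from independent normals
with the observed group means and SDs (623.89/30.1 and 1368.31/41.61 mels
congruent; 593.63/29.98 and 1339.06/24.50 incongruent; no covariance is
published, so none is modelled), redrawn until the eligibility screen
passes — baseline F1 above / F2 below the accompanist for the congruent
group and vice versa — mirroring the exclusion of participants whose
baselines sat on the wrong side of their accompanist.

Because the dynamics are linear and the noise terms have zero mean, the
expected trajectory obeys the same recursion without noise. The package
evaluates it in closed form (`analytic_adaptation()`, a recursive-filter
convolution — a separate code path from the simulator loop) and uses it as
the oracle for parameter recovery: noiseless simulation matches it to
numerical precision, and noisy cohort means are unbiased around it. The
long-run fixed point of the recursion under a constant drive,
$x^\* = b(\gamma(A-B) - p)/(1 - a + b)$, is checked separately in a
long-hold design where the transient has died out; under the default
schedule block 2 has not reached steady state (the convergence drive is
still growing), which is why the oracle evaluates the full trajectory
rather than the fixed point.

Two qualitative consequences of the model are worth stating. First, with
the default parameters every simulated participant adapts — compensation
($\approx b/(1-a+b)$ of the 70-mel perturbation, i.e. most of it) dominates
the convergence drive, so "following" responses never reach significance.
Second, followers do emerge in a strong-convergence regime
($\gamma_\infty = 0.9$, $\tau_c = 100$), and only in the incongruent group:
the incongruent accompanist is the only one whose pull is aligned with the
perturbation, and only participants whose sampled baseline lies far from
that accompanist experience a convergence drive strong enough to overcome
error correction. The asymmetry (incongruent-only followers) is a geometric
property of the design that the simulator reproduces; the default-regime
absence of followers is a reminder that a single shared gain cannot produce
the full between-participant heterogeneity of real cohorts.

## What the simulator does not emulate

No timing or synchrony accuracy, F0, amplitude, speaking-rate or attention
effects; no per-participant variation in learning parameters (only
baselines vary); no trial-to-trial sentence-dependent formant structure
beyond an additive offset; no drift in the accompanist percept. Passing
recovery tests therefore shows the *metrics* are unbiased and correctly
implemented under known ground truth — not that real speakers follow this
model.

## Formant extraction

The acoustic stage mirrors standard practice for sentence-level formant
analysis. Voiced regions are found by short-time autocorrelation (40 ms
frames, 10 ms hop): a frame is voiced when its normalized autocorrelation
peaks above 0.45 at a lag in the 75–500 Hz pitch range; runs of voiced
frames merge, and segments under 30 ms are dropped. The signal is then
resampled to 11 kHz and fit with order-10 LPC (pre-emphasis 0.97, Hamming
window, autocorrelation method with Levinson–Durbin, `polyroot` on the
prediction polynomial). Roots with positive imaginary part give candidate
resonances (`f = arg(z)·fs/2π`, `bw = −ln|z|·fs/π`); candidates outside
90 Hz – (fs/2 − 50 Hz) or wider than 400 Hz are discarded, and F1/F2 are
the two lowest survivors, without a continuity tracker — sentence-level
averaging (in mels) smooths frame-level errors. The 11 kHz / order-10
combination allocates roughly two poles per kilohertz up to 5.5 kHz, the
usual setting for adult female speech.

Validation uses synthesized vowels: an impulse train with a natural pitch
declination (default ±10% across the vowel) and a −6 dB/octave source
rolloff, passed through two-pole resonators at the target F1 (80 Hz
bandwidth) and F2 (120 Hz), plus dummy resonators at 2.5 and 3.5 kHz
standing in for F3/F4. The declination matters: with a strictly periodic
source at a high fundamental (220 Hz), LPC estimates snap toward the
nearest harmonic — a real and well-known bias, not an implementation
fault — and a fixed comb leaves the envelope unsampled between harmonics.
Sweeping the fundamental moves the harmonics across the resonance so the
sentence-level mean samples the envelope itself. On a 70-point grid
(F1 450–750 Hz, F2 1200–1600 Hz, F0 180/220 Hz, 1-s vowels) extraction
recovers both formants within max(3%, 30 Hz) at over 95% of points; the
residual failures sit exactly where F1 falls halfway between harmonics of a
220 Hz fundamental.

The extraction functions operate on numeric waveforms plus a sampling rate;
generating fixtures (`synth_vowel()`) and analysing them needs no audio
file I/O.

## Inference

`one_sample_t()` and `welch_t()` are computed from their closed forms
(cross-checked against `stats::t.test` in the tests, which is never used in
the analysis path). Participants are classified on their final-hold-block
per-trial scores with a two-sided one-sample t-test at α = 0.05: adapter if
significantly above zero, follower if below, none otherwise — no
multiplicity correction across participants, matching how such counts are
conventionally reported. The group contrast is a linear mixed model on
per-trial scores with block, group and block × group fixed effects and
random intercepts for participant and sentence, fit by `lmerTest`; the
interaction is tested by likelihood ratio. Sentence intercepts are
near-redundant after sentence-matched normalisation, so singular fits are
expected; the package then drops the sentence term with a warning and
records the simplification. Block enters as a numeric trend by default; the
formula is a parameter, so a factor coding or random slopes can be swapped
in without touching the package.

## Numerical and design choices

- Mel formula: O'Shaughnessy constants (2595/700), the convention of
  real-time perturbation software; roundtrip with `mel_to_hz()` is exact to
  1e−9 relative across the speech range.
- Ramp shape: linear in trial index across the first 25 ramp-block trials.
- Trial indexing is 1-based everywhere ("trial 25 of block 3" means what it
  says).
- Accompanist voices are session-average pairs; per-sentence accompanist
  tables are out of scope.
- Zero change vectors score 0; zero-magnitude perturbations are an error
  for the projection (no direction exists).
- The cohort master seed fans out into independent per-participant
  sampling and simulation streams, so cohorts are reproducible and
  participants independent.
- Pipeline CSVs round mels to 3 decimals on disk (full precision in
  memory); reruns into a run directory resume from the existing simulation
  unless overwriting is forced.

Validation problem sizes: the projection oracle runs 10,200 random vectors
across three perturbation geometries; parameter recovery uses 100 seeded
cohorts of 31 participants; the congruency ordering uses 50 seeded cohort
pairs; classification type-I error uses 2,000 null participants of 50
trials. These sizes give Monte-Carlo error comfortably below the decision
thresholds they are checked against.

## Known limitations

- The simulator's single shared gain understates individual differences;
  only baselines vary across simulated participants.
- LPC harmonic bias at high F0 limits per-vowel accuracy to roughly 30 Hz
  near F1 for 220 Hz voices, as for any all-pole method without a
  pitch-synchronous or envelope-weighted refinement.
- The mixed-model structure (random intercepts, numeric block trend) is a
  reasonable default, not a canonical specification; conclusions about
  marginal significance should be checked under alternative codings.
- Published per-participant coefficients from real datasets are not
  reproducible from simulations; the package targets the *methods*, and its
  quantitative checks are against its own ground truth and closed forms.
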