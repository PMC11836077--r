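#' Synthesize a steady vowel with known formants
#'
#' Source-filter synthesis used as a ground-truth fixture for the formant
#' extraction stage: a glottal impulse train at `f0` is passed through
#' cascaded two-pole resonators at `f1` (80 Hz bandwidth) and `f2` (120 Hz
#' bandwidth), plus two higher dummy resonators that stand in for F3/F4 so
#' the spectral envelope is realistic for an all-pole fit. The output is
#' peak-normalized.
#'
#' @param f1,f2 Target formant frequencies in Hz (`f0 < f1 < f2 < fs/2`).
#' @param f0 Mean fundamental frequency in Hz.
#' @param duration Duration in seconds (0 gives an empty waveform).
#' @param sample_rate Sampling rate in Hz.
#' @param f0_glide Fractional linear drift of the fundamental across the
#'   vowel (default 20%, i.e., from `1.1*f0` down to `0.9*f0` over the
#'   vowel's course), emulating natural pitch declination over a sustained
#'   vowel. The drift moves the harmonics across the resonance envelope so
#'   that time-averaged spectral estimates sample the envelope rather than
#'   a fixed harmonic comb; set to 0 for a strictly periodic train.
#' @return Numeric waveform in `[-1, 1]`.
#' @examples
#' w <- synth_vowel(600, 1400, f0 = 200, duration = 0.3)
#' @export
synth_vowel <- function(f1, f2, f0 = 200, duration = 1, sample_rate = 16000,
                        f0_glide = 0.2) {
  stopifnot(is.numeric(f1), is.numeric(f2), is.numeric(f0),
            duration >= 0, sample_rate > 0, f0_glide >= 0, f0_glide < 1)
  if (!(f0 < f1 && f1 < f2 && f2 < sample_rate / 2)) {
    stop("require f0 < f1 < f2 < sample_rate/2", call. = FALSE)
  }
  n <- round(duration * sample_rate)
  if (n == 0) return(numeric(0))
  f0_inst <- f0 * (1 - f0_glide * (seq_len(n) / n - 0.5))
  phase <- cumsum(f0_inst / sample_rate)
  x <- as.numeric(c(1, diff(floor(phase)) > 0))
  # glottal-style -6 dB/oct source rolloff (net of radiation), as in speech
  x <- as.numeric(stats::filter(x, 0.97, method = "recursive"))
  resonators <- rbind(c(f1, 80), c(f2, 120), c(2500, 200), c(3500, 250))
  for (i in seq_len(nrow(resonators))) {
    fc <- resonators[i, 1]; bw <- resonators[i, 2]
    if (fc >= sample_rate / 2 - 100) next   # dummy above Nyquist: skip
    r <- exp(-pi * bw / sample_rate)
    theta <- 2 * pi * fc / sample_rate
    x <- as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                                  method = "recursive"))
  }
  x / max(abs(x))
}

#' Detect voiced segments by short-time autocorrelation
#'
#' Frames the signal (40 ms windows, 10 ms hop) and marks a frame voiced
#' when its normalized autocorrelation has a peak above `threshold` at some
#' lag inside the plausible pitch range (75-500 Hz). Adjacent voiced frames
#' merge into segments; segments shorter than `min_duration` are dropped.
#' Normalized autocorrelation is invariant to amplitude scaling, so the
#' detector is too.
#'
#' @param wave Mono numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param frame Frame length in seconds.
#' @param hop Hop between frame starts in seconds.
#' @param f0_range Pitch search range in Hz, `c(low, high)`.
#' @param threshold Voicing decision threshold on the normalized
#'   autocorrelation peak.
#' @param min_duration Minimum retained segment duration in seconds.
#' @return Data.frame with columns `start`, `end` (seconds), sorted and
#'   non-overlapping; zero rows when nothing is voiced.
#' @export
detect_voiced <- function(wave, sample_rate, frame = 0.040, hop = 0.010,
                          f0_range = c(75, 500), threshold = 0.45,
                          min_duration = 0.030) {
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (!length(wave)) return(empty)
  L <- round(frame * sample_rate)
  H <- round(hop * sample_rate)
  if (length(wave) < L) return(empty)
  lags <- seq(max(1L, floor(sample_rate / f0_range[2])),
              min(L - 1L, ceiling(sample_rate / f0_range[1])))
  starts <- seq(1L, length(wave) - L + 1L, by = H)
  voiced <- vapply(starts, function(s) {
    x <- wave[s:(s + L - 1L)]
    x <- x - mean(x)
    r0 <- sum(x * x)
    if (r0 <= 0) return(FALSE)
    peak <- max(vapply(lags, function(l) {
      sum(x[1:(L - l)] * x[(l + 1):L])
    }, numeric(1))) / r0
    peak > threshold
  }, logical(1))
  if (!any(voiced)) return(empty)
  # merge runs of voiced frames into segments
  r <- rle(voiced)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- which(r$values)
  seg <- data.frame(
    start = (starts[starts_idx[keep]] - 1L) / sample_rate,
    end = (starts[ends_idx[keep]] - 1L + L) / sample_rate
  )
  seg <- seg[seg$end - seg$start >= min_duration, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Levinson-Durbin recursion
#'
#' Solves the autocorrelation normal equations for the linear-prediction
#' coefficients: returns `a` such that `x_t ~ sum_k a_k x_{t-k}` minimizes
#' the prediction error under the given autocorrelation sequence.
#'
#' @param r Autocorrelation sequence `r[1] = r(0), ..., r[order+1] =
#'   r(order)`.
#' @param order Prediction order (`length(r) >= order + 1`).
#' @return List with `a` (predictor coefficients, length `order`) and `err`
#'   (final prediction-error power).
#' @export
levinson_durbin <- function(r, order) {
  stopifnot(length(r) >= order + 1, order >= 1)
  if (r[1] <= 0) stop("autocorrelation not positive-definite", call. = FALSE)
  a <- numeric(order)
  err <- r[1]
  for (m in seq_len(order)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a[1:(m - 1)] * r[m:2])
    k <- acc / err
    new_a <- a
    new_a[m] <- k
    if (m > 1) new_a[1:(m - 1)] <- a[1:(m - 1)] - k * a[(m - 1):1]
    a <- new_a
    err <- err * (1 - k^2)
    if (err <= 0) stop("unstable recursion: non-positive prediction error",
                       call. = FALSE)
  }
  list(a = a, err = err)
}

#' LPC formant estimates for one frame
#'
#' Autocorrelation-method linear predictive coding: pre-emphasis (0.97),
#' Hamming window, biased autocorrelation, [levinson_durbin()], then the
#' roots of the prediction polynomial. Roots with positive imaginary part
#' map to candidate resonances with `frequency = arg(z) * fs / (2*pi)` and
#' `bandwidth = -log(|z|) * fs / pi`; candidates are retained when
#' `90 Hz < f < fs/2 - 50 Hz` and bandwidth `< 400 Hz`, and returned in
#' ascending frequency order.
#'
#' @param frame Numeric frame (length `>= 2 * order`).
#' @param sample_rate Sampling rate in Hz.
#' @param order LPC order.
#' @param preemphasis First-order pre-emphasis coefficient.
#' @return Data.frame `frequency`, `bandwidth` (Hz), ascending in frequency.
#' @export
lpc_formants <- function(frame, sample_rate, order = 10, preemphasis = 0.97) {
  stopifnot(length(frame) >= 2 * order)
  x <- frame - mean(frame)
  x <- c(x[1], x[-1] - preemphasis * x[-length(x)])
  x <- x * signal::hamming(length(x))
  r <- vapply(0:order, function(l) {
    sum(x[1:(length(x) - l)] * x[(l + 1):length(x)]) / length(x)
  }, numeric(1))
  ld <- levinson_durbin(r, order)
  z <- 1 / polyroot(c(1, -ld$a))   # poles of the all-pole model
  z <- z[Im(z) > 0]
  freq <- Arg(z) * sample_rate / (2 * pi)
  bw <- -log(Mod(z)) * sample_rate / pi
  keep <- freq > 90 & freq < sample_rate / 2 - 50 & bw < 400 & bw > 0
  out <- data.frame(frequency = freq[keep], bandwidth = bw[keep])
  out[order(out$frequency), , drop = FALSE]
}

#' Mean sentence F1/F2 in mels from a waveform
#'
#' The full acoustic-analysis chain for one recorded sentence: voiced
#' regions are isolated by autocorrelation ([detect_voiced()]), the signal
#' is resampled to an analysis rate suited to a two-formant-per-kHz all-pole
#' fit, F1/F2 are taken frame-by-frame as the two lowest retained LPC roots
#' ([lpc_formants()]), converted to mels, and averaged over all voiced
#' frames.
#'
#' @param wave Mono numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param analysis_rate Internal LPC analysis rate in Hz.
#' @param order LPC order at the analysis rate.
#' @param frame,hop Analysis frame length and hop in seconds.
#' @return A [formant_pair()] in mels, with attribute `n_frames` (voiced
#'   frames analysed).
#' @export
sentence_formants <- function(wave, sample_rate, analysis_rate = 11000,
                              order = 10, frame = 0.040, hop = 0.010) {
  segs <- detect_voiced(wave, sample_rate)
  if (!nrow(segs)) {
    stop("no voiced segments: trial is unanalyzable", call. = FALSE)
  }
  if (analysis_rate != sample_rate) {
    g <- gcd(analysis_rate, sample_rate)
    wave <- as.numeric(signal::resample(wave, analysis_rate / g,
                                        sample_rate / g))
    sample_rate <- analysis_rate
  }
  L <- round(frame * sample_rate)
  H <- round(hop * sample_rate)
  f1 <- c(); f2 <- c()
  for (i in seq_len(nrow(segs))) {
    s0 <- max(1L, round(segs$start[i] * sample_rate) + 1L)
    s1 <- min(length(wave), round(segs$end[i] * sample_rate))
    if (s1 - s0 + 1L < L) next
    for (s in seq(s0, s1 - L + 1L, by = H)) {
      fr <- tryCatch(lpc_formants(wave[s:(s + L - 1L)], sample_rate, order),
                     error = function(e) NULL)
      if (!is.null(fr) && nrow(fr) >= 2) {
        f1 <- c(f1, fr$frequency[1])
        f2 <- c(f2, fr$frequency[2])
      }
    }
  }
  if (!length(f1)) {
    stop("no analyzable voiced frames: trial is unanalyzable", call. = FALSE)
  }
  out <- formant_pair(mean(hz_to_mel(f1)), mean(hz_to_mel(f2)), unit = "mel")
  attr(out, "n_frames") <- length(f1)
  out
}

gcd <- function(a, b) if (b == 0) a else Recall(b, a %% b)
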