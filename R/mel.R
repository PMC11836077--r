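#' Convert frequency from Hertz to mels
#'
#' Uses the O'Shaughnessy mel scale, `m = 2595 * log10(1 + f/700)`
#' (equivalently `1127 * log(1 + f/700)`), the convention used by real-time
#' formant-perturbation software. The mel scale is approximately linear below
#' 1 kHz and logarithmic above, so formant shifts expressed in mels are
#' roughly perceptually uniform across the vowel space.
#'
#' @param f Numeric vector of frequencies in Hz; must be non-negative.
#' @return Numeric vector of frequencies in mels.
#' @seealso [mel_to_hz()]
#' @examples
#' hz_to_mel(c(0, 700, 1000))
#' @export
hz_to_mel <- function(f) {
  if (!is.numeric(f)) stop("`f` must be numeric", call. = FALSE)
  if (any(f < 0, na.rm = TRUE)) stop("frequencies must be >= 0", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' Convert frequency from mels to Hertz
#'
#' Inverse of [hz_to_mel()].
#'
#' @param m Numeric vector of frequencies in mels; must be non-negative.
#' @return Numeric vector of frequencies in Hz.
#' @export
mel_to_hz <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("frequencies must be >= 0", call. = FALSE)
  700 * (10^(m / 2595) - 1)
}

#' Construct a unit-tagged F1/F2 formant pair
#'
#' A light container for one vowel measurement: first and second formant,
#' tagged with the frequency unit so mel/Hz values are never silently mixed.
#'
#' @param f1,f2 First and second formant frequencies (scalars, `f2 > f1 > 0`).
#' @param unit `"mel"` or `"hz"`.
#' @return An object of class `formant_pair`: a named numeric vector
#'   `c(f1, f2)` with a `unit` attribute.
#' @examples
#' formant_pair(600, 1400, unit = "mel")
#' @export
formant_pair <- function(f1, f2, unit = c("mel", "hz")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(f1), is.numeric(f2), length(f1) == 1, length(f2) == 1)
  if (!(f1 > 0 && f2 > f1)) {
    stop("a physical vowel requires 0 < f1 < f2", call. = FALSE)
  }
  structure(c(f1 = f1, f2 = f2), unit = unit, class = "formant_pair")
}

#' @export
print.formant_pair <- function(x, ...) {
  cat(sprintf("<formant_pair> F1 = %.2f, F2 = %.2f [%s]\n",
              x[["f1"]], x[["f2"]], attr(x, "unit")))
  invisible(x)
}

formant_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "mel" else u
}

# Coerce a length-2 numeric or formant_pair to a plain c(f1, f2) in mels,
# erroring on a Hz-tagged pair where mels are required.
as_mel_pair <- function(x, arg = "pair") {
  if (inherits(x, "formant_pair") && formant_unit(x) != "mel") {
    stop(sprintf("`%s` must be in mels, got unit '%s'", arg, formant_unit(x)),
         call. = FALSE)
  }
  v <- unname(as.numeric(x))
  if (length(v) != 2 || any(!is.finite(v))) {
    stop(sprintf("`%s` must be a finite (f1, f2) pair", arg), call. = FALSE)
  }
  v
}
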