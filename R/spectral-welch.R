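#' Construct a normalized spectrum estimate
#'
#' Mostly internal: wraps a frequency grid and power values as an
#' `egm_spectrum` tibble, renormalizing the power values to unit area so
#' that `sum(pn) * resolution == 1`.
#'
#' @param freq Strictly increasing frequency grid (Hz), uniform step.
#' @param power Non-negative power values on that grid.
#' @param fs Sampling rate in Hz.
#' @param mainlobe Effective resolution in Hz (fs/256 for the Welch scheme).
#' @param n_segments Number of averaged segments (metadata).
#' @return A tibble of class `egm_spectrum` with columns `freq`, `pn`.
#' @export
egm_spectrum <- function(freq, power, fs, mainlobe = fs / 256,
                         n_segments = NA_integer_) {
  if (any(diff(freq) <= 0)) abort("`freq` must be strictly increasing.")
  if (any(power < 0)) abort("`power` must be non-negative.")
  resolution <- freq[2] - freq[1]
  total <- sum(power) * resolution
  if (total <= 0) abort("Spectrum has zero total power.")
  out <- tibble(freq = freq, pn = power / total)
  structure(out,
            fs = fs, resolution = resolution, mainlobe = mainlobe,
            n_segments = n_segments,
            class = c("egm_spectrum", class(out)))
}

#' Averaged Welch periodogram, normalized to unit area
#'
#' The estimation scheme is fixed to the study's convention: the
#' mean-removed signal is split into 256-sample segments with 50% overlap
#' (hop 128), each segment is tapered with a rectangular window (i.e. left
#' untouched, for maximum spectral resolution), zero-padded to a 4096-point
#' transform, and the one-sided segment periodograms are averaged and
#' normalized to unit area so the result is a density in 1/Hz. A 600-sample
#' (3 s at 200 Hz) window yields exactly 3 segments. The frequency grid step
#' is fs/4096 and the effective resolution (mainlobe width) fs/256.
#'
#' @param rec An [egm_recording()], or a numeric vector with `fs` supplied.
#' @param fs Sampling rate in Hz (only when `rec` is a bare vector).
#' @param seg_len Segment length in samples (default 256).
#' @param nfft Transform support (default 4096).
#' @return An `egm_spectrum` tibble (`freq` in Hz from 0 to fs/2, `pn` in
#'   1/Hz) with attributes `resolution`, `mainlobe`, `n_segments`.
#' @examples
#' rec <- egm_recording(sin(2 * pi * 5 * (0:599) / 200))
#' spec <- welch_psd(rec)
#' spec$freq[which.max(spec$pn)]
#' @export
welch_psd <- function(rec, fs = NULL, seg_len = 256L, nfft = 4096L) {
  if (inherits(rec, "egm_recording")) {
    fs <- attr(rec, "fs")
    x <- rec$value
  } else {
    if (is.null(fs)) abort("Supply `fs` when `rec` is a bare numeric vector.")
    x <- as.numeric(rec)
  }
  n <- length(x)
  if (n < seg_len) {
    abort(sprintf("Need at least %d samples for the Welch estimate, got %d.",
                  seg_len, n))
  }
  x <- x - mean(x)
  hop <- seg_len %/% 2L
  n_seg <- (n - seg_len) %/% hop + 1L
  starts <- (seq_len(n_seg) - 1L) * hop + 1L
  segs <- vapply(starts, function(s) x[s:(s + seg_len - 1L)], numeric(seg_len))
  padded <- rbind(segs, matrix(0, nfft - seg_len, n_seg))
  X <- stats::mvfft(padded)
  half <- nfft %/% 2L + 1L
  p <- rowMeans(Mod(X[seq_len(half), , drop = FALSE])^2)
  freq <- (seq_len(half) - 1L) * fs / nfft
  egm_spectrum(freq, p, fs = fs, mainlobe = fs / seg_len, n_segments = n_seg)
}
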