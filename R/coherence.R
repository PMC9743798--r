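#' Welch magnitude-squared coherence between two uniform series
#'
#' Estimates `Cxy(f) = |Pxy(f)|^2 / (Pxx(f) * Pyy(f))` with Welch's
#' method: both series are cut into tapered segments of `window_len`
#' samples with fractional `overlap`, each segment is zero-padded to
#' `nfft` points and transformed, and the auto- and cross-spectra are
#' averaged across segments before forming the ratio. With a single
#' segment the estimator is identically 1, so at least two averaging
#' segments are required. Frequencies run from 0 to `fs/2`
#' (0.25 Hz at the 0.5 Hz resampling rate) with spacing `fs/nfft`.
#'
#' @param m,f normalized `uniform_series` (or numeric vectors) of equal
#'   length, at least `2 * window_len` samples.
#' @param window_len Welch segment length, samples (default 10).
#' @param fs sampling rate, Hz (default 0.5; taken from the series when
#'   available).
#' @param taper `"hamming"` (default) or `"hann"` segment taper.
#' @param overlap fractional segment overlap (default 0.5).
#' @param nfft FFT length; segments are zero-padded (default 256).
#' @return object of class `coherence_spectrum`: list with `freq` (Hz,
#'   ascending, last element `fs/2`), `msc` (values in `[0, 1]`),
#'   `n_segments`.
#' @export
msc_spectrum <- function(m, f, window_len = 10, fs = NULL,
                         taper = c("hamming", "hann"), overlap = 0.5,
                         nfft = 256) {
  taper <- match.arg(taper)
  x <- series_values(m, "m")
  y <- series_values(f, "f")
  if (is.null(fs)) {
    fs <- if (inherits(m, "uniform_series") && is.finite(m$fs)) m$fs else 0.5
  }
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  n <- length(x)
  if (n < 2L * window_len)
    stop("series shorter than 2 windows; coherence undefined")
  step <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, n - window_len + 1L, by = step)
  if (length(starts) < 2L)
    stop("undefined coherence: fewer than 2 averaging segments ",
         "(single-segment coherence is identically 1)")
  if (nfft < window_len)
    stop("nfft must be >= window_len")
  w <- if (taper == "hamming") as.numeric(signal::hamming(window_len))
       else as.numeric(signal::hanning(window_len))
  pxx <- pyy <- numeric(nfft)
  pxy <- complex(nfft)
  for (s in starts) {
    idx <- s:(s + window_len - 1L)
    xs <- c(w * x[idx], numeric(nfft - window_len))
    ys <- c(w * y[idx], numeric(nfft - window_len))
    fx <- stats::fft(xs)
    fy <- stats::fft(ys)
    pxx <- pxx + Re(fx * Conj(fx))
    pyy <- pyy + Re(fy * Conj(fy))
    pxy <- pxy + fx * Conj(fy)
  }
  half <- 1L:(nfft %/% 2L + 1L)
  msc <- Mod(pxy[half])^2 / (pxx[half] * pyy[half])
  msc[!is.finite(msc)] <- NA_real_
  structure(list(freq = (half - 1L) * fs / nfft, msc = msc,
                 n_segments = length(starts)),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, 0-%.3g Hz, %d Welch segments\n",
              length(x$freq), max(x$freq), x$n_segments))
  invisible(x)
}

#' Band-averaged coherence (CLF, CHF)
#'
#' Averages the magnitude-squared coherence over the low-frequency band
#' (default 0.04-0.15 Hz) and the high-frequency band (default
#' 0.15-0.25 Hz). The shared band edge is counted once: LF bins satisfy
#' `lo <= f < hi`, HF bins `lo <= f <= hi`.
#'
#' @param spec a [msc_spectrum()] result.
#' @param lf_band,hf_band band limits, Hz.
#' @return list with `clf` and `chf`, each in `[0, 1]`.
#' @export
band_coherence <- function(spec, lf_band = c(0.04, 0.15),
                           hf_band = c(0.15, 0.25)) {
  stopifnot(inherits(spec, "coherence_spectrum"))
  lf_sel <- spec$freq >= lf_band[1L] & spec$freq < lf_band[2L]
  hf_sel <- spec$freq >= hf_band[1L] & spec$freq <= hf_band[2L]
  df <- if (length(spec$freq) > 1L) spec$freq[2L] - spec$freq[1L] else NA
  if (!any(lf_sel))
    stop("LF band contains no frequency bin (bin spacing ", df, " Hz)")
  if (!any(hf_sel))
    stop("HF band contains no frequency bin (bin spacing ", df, " Hz)")
  list(clf = mean(spec$msc[lf_sel], na.rm = TRUE),
       chf = mean(spec$msc[hf_sel], na.rm = TRUE))
}
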