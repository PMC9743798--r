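#' Similarity-analysis configuration
#'
#' Collects the tunable parameters of the epoch scoring pipeline. Defaults
#' reproduce the standard analysis: 2-s resampling bins (0.5 Hz), 10-sample
#' windows for the cross-correlation (9 windows per 3-minute epoch), Welch
#' coherence with a 10-sample Hamming-tapered segment, 50% overlap and a
#' 256-point FFT, and LF/HF coherence bands of 0.04-0.15 Hz and
#' 0.15-0.25 Hz.
#'
#' @param bin_width_ms resampling bin width, ms. Must be at least as long
#'   as the largest plausible RR interval so every bin holds a beat
#'   (2 s accommodates mean fetal RRI up to ~1 s).
#' @param window_len cross-correlation / Welch segment length, samples.
#' @param fs sampling rate of the resampled series, Hz (`1000 / bin_width_ms`
#'   by construction; kept explicit because the coherence frequency axis
#'   depends on it).
#' @param lf_band,hf_band coherence bands, Hz. The shared 0.15 Hz edge is
#'   counted once: LF is half-open `[lo, hi)`, HF closed at the top
#'   `[lo, hi]`.
#' @param lag_policy `"zero"` keeps the zero-lag normalized
#'   cross-correlation coefficient per window (signed, as CC2 requires);
#'   `"max_abs"` keeps the coefficient of largest magnitude across lags.
#' @param center_windows if `TRUE`, re-centre each window before the
#'   cross-correlation. Off by default: normalization subtracts the epoch
#'   mean once, then the series is cut into windows.
#' @param welch_taper,welch_overlap,welch_nfft Welch coherence details:
#'   taper (`"hamming"` or `"hann"`), fractional segment overlap, FFT
#'   length (zero-padded).
#' @param gap_policy what to do with a resampling bin containing no beat:
#'   `"error"` (default) or `"interpolate"` (linear, from neighbouring
#'   bins).
#' @return a list of class `similarity_config`.
#' @export
similarity_config <- function(bin_width_ms = 2000, window_len = 10, fs = 0.5,
                              lf_band = c(0.04, 0.15),
                              hf_band = c(0.15, 0.25),
                              lag_policy = c("zero", "max_abs"),
                              center_windows = FALSE,
                              welch_taper = c("hamming", "hann"),
                              welch_overlap = 0.5, welch_nfft = 256,
                              gap_policy = c("error", "interpolate")) {
  structure(list(bin_width_ms = bin_width_ms, window_len = window_len,
                 fs = fs, lf_band = lf_band, hf_band = hf_band,
                 lag_policy = match.arg(lag_policy),
                 center_windows = center_windows,
                 welch_taper = match.arg(welch_taper),
                 welch_overlap = welch_overlap, welch_nfft = welch_nfft,
                 gap_policy = match.arg(gap_policy)),
            class = "similarity_config")
}

#' Resample a tachogram onto a uniform grid by per-bin averaging
#'
#' Bin k of the output is the mean of all RR intervals whose terminating
#' beat falls in `[start + k*bin, start + (k+1)*bin)`. A 3-minute epoch at
#' 2-s bins yields exactly 90 samples. The bin width must exceed the
#' largest plausible RRI so that bins are non-empty; an empty bin is an
#' error unless `gap_policy = "interpolate"`.
#'
#' @param tach an [rri_tachogram] covering the epoch.
#' @param start_ms,end_ms epoch bounds, ms. May be given implicitly via
#'   `epoch`.
#' @param epoch optional [rri_epoch]; its bounds override
#'   `start_ms`/`end_ms`.
#' @param bin_width_ms bin width, ms (default 2000).
#' @param gap_policy `"error"` or `"interpolate"`.
#' @return object of class `uniform_series`: list with `values` (per-bin
#'   mean RRI, ms), `fs` (Hz), `normalized = FALSE`.
#' @export
resample_uniform <- function(tach, start_ms = NULL, end_ms = NULL,
                             epoch = NULL, bin_width_ms = 2000,
                             gap_policy = c("error", "interpolate")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(tach, "rri_tachogram"))
  if (!is.null(epoch)) {
    start_ms <- epoch$start_ms
    end_ms <- epoch$end_ms
  }
  stopifnot(is.numeric(start_ms), is.numeric(end_ms), end_ms > start_ms)
  n_bins <- floor((end_ms - start_ms) / bin_width_ms)
  if (n_bins < 1L)
    stop("epoch shorter than one bin")
  sel <- tach$time_ms >= start_ms & tach$time_ms < start_ms + n_bins * bin_width_ms
  t <- tach$time_ms[sel]
  r <- tach$rri_ms[sel]
  bin <- floor((t - start_ms) / bin_width_ms) + 1L
  sums <- tabulate_sum(bin, r, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  values <- sums / counts
  if (any(counts == 0L)) {
    empty <- which(counts == 0L)
    if (gap_policy == "error")
      stop("empty resampling bin(s): ", paste(empty, collapse = ", "),
           " (no beat in a ", bin_width_ms, " ms bin)")
    filled <- which(counts > 0L)
    if (length(filled) < 2L)
      stop("cannot interpolate: fewer than 2 non-empty bins")
    values[empty] <- stats::approx(filled, values[filled], xout = empty,
                                   rule = 2)$y
  }
  structure(list(values = values, fs = 1000 / bin_width_ms,
                 normalized = FALSE),
            class = "uniform_series")
}

tabulate_sum <- function(bin, x, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples at %.3g Hz (%s)\n",
              length(x$values), x$fs,
              if (isTRUE(x$normalized)) "normalized" else "raw, ms"))
  invisible(x)
}

#' Amplitude-normalize a uniform series
#'
#' Subtracts the series mean and divides by the maximum absolute deviation:
#' `out = (x - mean(x)) / max(|x - mean(x)|)`. The result has mean zero and
#' maximum absolute value exactly one, making maternal and fetal series
#' directly comparable regardless of their very different RRI scales.
#'
#' @param series a raw [resample_uniform()] output (or any numeric vector).
#' @return a normalized `uniform_series`.
#' @export
normalize_series <- function(series) {
  if (inherits(series, "uniform_series")) {
    if (isTRUE(series$normalized))
      stop("series is already normalized")
    x <- series$values
    fs <- series$fs
  } else {
    x <- as.numeric(series)
    fs <- NA_real_
  }
  centred <- x - mean(x)
  denom <- max(abs(centred))
  if (denom == 0)
    stop("degenerate signal: constant input cannot be normalized")
  structure(list(values = centred / denom, fs = fs, normalized = TRUE),
            class = "uniform_series")
}

#' Windowed zero-lag normalized cross-correlation
#'
#' Cuts both normalized series into consecutive non-overlapping windows of
#' `window_len` samples and computes, per window,
#' `r_w = sum(m*f) / sqrt(sum(m^2) * sum(f^2))` — the zero-lag coefficient
#' of the normalized cross-correlation. Ninety samples at window 10 yield
#' 9 coefficients. Windows are not re-centred by default (the epoch mean
#' was already removed by normalization); a window that is identically zero
#' in either signal has an undefined coefficient and is recorded as `NA`.
#'
#' @param m,f normalized `uniform_series` (or numeric vectors) of equal
#'   length.
#' @param window_len window length, samples (default 10). A trailing
#'   remainder shorter than `window_len` is dropped with a warning.
#' @param lag_policy `"zero"` (default) or `"max_abs"` (coefficient of
#'   largest magnitude over all lags within the window).
#' @param center_windows re-centre each window first (default `FALSE`).
#' @return object of class `windowed_cc`: list with `r` (coefficients,
#'   possibly `NA`), `window_len`, `n_valid`, `n_dropped_windows`.
#' @export
windowed_cc <- function(m, f, window_len = 10,
                        lag_policy = c("zero", "max_abs"),
                        center_windows = FALSE) {
  lag_policy <- match.arg(lag_policy)
  mv <- series_values(m, "m")
  fv <- series_values(f, "f")
  if (length(mv) != length(fv))
    stop("series lengths differ: ", length(mv), " vs ", length(fv))
  n <- length(mv)
  n_win <- n %/% window_len
  if (n_win < 1L)
    stop("series shorter than one window")
  if (n %% window_len != 0L)
    warning("dropping trailing ", n %% window_len,
            " samples not filling a window")
  r <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * window_len + 1L):(w * window_len)
    a <- mv[idx]
    b <- fv[idx]
    if (center_windows) {
      a <- a - mean(a)
      b <- b - mean(b)
    }
    ea <- sum(a^2)
    eb <- sum(b^2)
    if (ea == 0 || eb == 0) {
      r[w] <- NA_real_
      next
    }
    r[w] <- if (lag_policy == "zero") {
      sum(a * b) / sqrt(ea * eb)
    } else {
      cc <- full_xcorr(a, b) / sqrt(ea * eb)
      cc[which.max(abs(cc))]
    }
  }
  n_na <- sum(is.na(r))
  if (n_na > 0L)
    warning(n_na, " degenerate window(s) excluded from CC averaging")
  structure(list(r = r, window_len = window_len,
                 n_valid = n_win - n_na, n_dropped_windows = n_na),
            class = "windowed_cc")
}

# cross-correlation at all lags -(n-1)..(n-1), unnormalized
full_xcorr <- function(a, b) {
  n <- length(a)
  vapply(-(n - 1L):(n - 1L), function(l) {
    if (l >= 0) sum(a[(1L + l):n] * b[1L:(n - l)])
    else sum(a[1L:(n + l)] * b[(1L - l):n])
  }, numeric(1))
}

series_values <- function(x, what) {
  if (inherits(x, "uniform_series")) {
    if (!isTRUE(x$normalized))
      stop("series '", what, "' must be normalized first")
    x$values
  } else {
    as.numeric(x)
  }
}

#' @export
print.windowed_cc <- function(x, ...) {
  cat(sprintf("<windowed_cc> %d windows of %d samples (%d valid)\n",
              length(x$r), x$window_len, x$n_valid))
  print(round(x$r, 3))
  invisible(x)
}

#' Epoch-level cross-correlation scores
#'
#' CC1 is the mean of the absolute per-window coefficients (overall
#' similarity strength regardless of direction, in `[0, 1]`); CC2 is the
#' signed mean (net direction of the similarity, in `[-1, 1]`). Undefined
#' windows are excluded from both means.
#'
#' @param wcc a [windowed_cc] result.
#' @return list with `cc1`, `cc2`, `n_valid`. If no window is valid, both
#'   scores are `NA`.
#' @export
cc_scores <- function(wcc) {
  stopifnot(inherits(wcc, "windowed_cc"))
  r <- wcc$r[!is.na(wcc$r)]
  if (length(r) == 0L)
    return(list(cc1 = NA_real_, cc2 = NA_real_, n_valid = 0L))
  list(cc1 = mean(abs(r)), cc2 = mean(r), n_valid = length(r))
}
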