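#' Score the maternal-fetal similarity of one epoch
#'
#' The central estimator of the package. For one shared artifact-free
#' epoch it chains: per-2-s-bin resampling of both tachograms, amplitude
#' normalization, windowed zero-lag normalized cross-correlation (summarized
#' as CC1, the mean absolute coefficient, and CC2, the signed mean), and
#' Welch magnitude-squared coherence summarized as the band means CLF
#' (0.04-0.15 Hz) and CHF (0.15-0.25 Hz).
#'
#' @param epoch an [rri_epoch]; alternatively pass `maternal` and `fetal`
#'   tachograms already restricted to a shared window.
#' @param config a [similarity_config()].
#' @param maternal,fetal optional [rri_tachogram]s used with `start_ms` and
#'   `end_ms` when no epoch object is supplied.
#' @param start_ms,end_ms epoch bounds when tachograms are passed directly.
#' @return an object of class `mf_similarity` with components
#'   `cc1`, `cc2`, `clf`, `chf`, `windows` (the [windowed_cc]),
#'   `spectrum` (the [msc_spectrum()] result), `maternal`/`fetal`
#'   (normalized `uniform_series`), `n_valid_windows`, `config`, `epoch`.
#' @examples
#' dyad <- simulate_dyad(dyad_params(coupling_rho = 0.9, duration_s = 300,
#'                                   seed = 1))
#' ep <- rri_epoch(beats_to_rri(dyad$maternal), beats_to_rri(dyad$fetal),
#'                 60000, 240000)
#' fit <- score_epoch(ep)
#' coef(fit)
#' @export
score_epoch <- function(epoch = NULL, config = similarity_config(),
                        maternal = NULL, fetal = NULL,
                        start_ms = NULL, end_ms = NULL) {
  if (is.null(epoch)) {
    stopifnot(!is.null(maternal), !is.null(fetal),
              !is.null(start_ms), !is.null(end_ms))
    epoch <- rri_epoch(maternal, fetal, start_ms, end_ms)
  }
  stopifnot(inherits(epoch, "rri_epoch"), inherits(config, "similarity_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("similarity stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mu <- stage("resample maternal",
              resample_uniform(epoch$maternal, epoch = epoch,
                               bin_width_ms = config$bin_width_ms,
                               gap_policy = config$gap_policy))
  fu <- stage("resample fetal",
              resample_uniform(epoch$fetal, epoch = epoch,
                               bin_width_ms = config$bin_width_ms,
                               gap_policy = config$gap_policy))
  mn <- stage("normalize maternal", normalize_series(mu))
  fn <- stage("normalize fetal", normalize_series(fu))
  wcc <- stage("windowed cross-correlation",
               windowed_cc(mn, fn, window_len = config$window_len,
                           lag_policy = config$lag_policy,
                           center_windows = config$center_windows))
  cc <- cc_scores(wcc)
  spec <- stage("coherence",
                msc_spectrum(mn, fn, window_len = config$window_len,
                             fs = config$fs, taper = config$welch_taper,
                             overlap = config$welch_overlap,
                             nfft = config$welch_nfft))
  bands <- stage("band coherence",
                 band_coherence(spec, lf_band = config$lf_band,
                                hf_band = config$hf_band))
  structure(list(cc1 = cc$cc1, cc2 = cc$cc2,
                 clf = bands$clf, chf = bands$chf,
                 windows = wcc, spectrum = spec,
                 maternal = mn, fetal = fn,
                 n_valid_windows = cc$n_valid,
                 config = config, epoch = epoch),
            class = "mf_similarity")
}

#' @export
print.mf_similarity <- function(x, digits = 3, ...) {
  cat("Maternal-fetal RRI similarity\n")
  cat(sprintf("  epoch: [%.0f, %.0f] ms (%.0f s), %d valid CC windows\n",
              x$epoch$start_ms, x$epoch$end_ms,
              (x$epoch$end_ms - x$epoch$start_ms) / 1000,
              x$n_valid_windows))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.mf_similarity <- function(object, ...) {
  c(cc1 = object$cc1, cc2 = object$cc2,
    clf = object$clf, chf = object$chf)
}

#' @export
summary.mf_similarity <- function(object, ...) {
  structure(list(scores = coef(object),
                 window_r = object$windows$r,
                 n_valid_windows = object$n_valid_windows,
                 n_samples = length(object$maternal$values),
                 n_segments = object$spectrum$n_segments,
                 freq_max = max(object$spectrum$freq)),
            class = "summary.mf_similarity")
}

#' @export
print.summary.mf_similarity <- function(x, digits = 3, ...) {
  cat("Maternal-fetal RRI similarity\n")
  cat(sprintf("  %d resampled samples; %d/%d valid CC windows; %d Welch segments (max freq %.3g Hz)\n",
              x$n_samples, x$n_valid_windows, length(x$window_r),
              x$n_segments, x$freq_max))
  cat("Scores:\n")
  print(round(x$scores, digits))
  cat("Per-window coefficients:\n")
  print(round(x$window_r, digits))
  invisible(x)
}

#' Plot a scored epoch
#'
#' Three panels: the normalized maternal and fetal series on the 2-s grid,
#' the per-window cross-correlation coefficients, and the coherence
#' spectrum with the LF/HF bands shaded.
#'
#' @param x an `mf_similarity` object.
#' @param ... ignored.
#' @export
plot.mf_similarity <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- seq_along(x$maternal$values) * (1 / x$maternal$fs)
  graphics::plot(tt, x$maternal$values, type = "l", col = "blue",
                 xlab = "time (s)", ylab = "normalized RRI",
                 main = "Normalized maternal (blue) and fetal (red) RRI",
                 ylim = c(-1, 1))
  graphics::lines(tt, x$fetal$values, col = "red")
  wl <- x$windows$window_len / x$maternal$fs
  centers <- (seq_along(x$windows$r) - 0.5) * wl
  graphics::plot(centers, x$windows$r, type = "h", lwd = 3,
                 ylim = c(-1, 1), xlab = "time (s)",
                 ylab = "window r",
                 main = sprintf("Per-window CC (CC1 = %.2f, CC2 = %.2f)",
                                x$cc1, x$cc2))
  graphics::abline(h = 0, lty = 3)
  graphics::plot(x$spectrum$freq, x$spectrum$msc, type = "l",
                 ylim = c(0, 1), xlab = "frequency (Hz)", ylab = "MSC",
                 main = sprintf("Coherence (CLF = %.2f, CHF = %.2f)",
                                x$clf, x$chf))
  cfg <- x$config
  graphics::rect(cfg$lf_band[1], 0, cfg$lf_band[2], 1,
                 col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  graphics::rect(cfg$hf_band[1], 0, cfg$hf_band[2], 1,
                 col = grDevices::adjustcolor("tomato", 0.15), border = NA)
  invisible(x)
}
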