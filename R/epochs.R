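#' Quality-screening configuration for epoch selection
#'
#' The screening rule is a deterministic stand-in for the manual "no noise
#' or consistent arrhythmia" inspection: a window fails if any RR interval
#' deviates from the window median by more than `max_dev_frac`, or falls
#' outside a physiological band. Default bands: maternal 50-300 ms,
#' fetal 200-1100 ms (the fetal band brackets the 306-981 ms range of mean
#' fetal RRI observed in anesthetized pregnant mice).
#'
#' @param max_dev_frac maximal fractional deviation from the window median
#'   (default 0.30).
#' @param maternal_band,fetal_band admissible RRI ranges, ms.
#' @return a list of class `quality_config`.
#' @export
quality_config <- function(max_dev_frac = 0.30,
                           maternal_band = c(50, 300),
                           fetal_band = c(200, 1100)) {
  stopifnot(max_dev_frac > 0, length(maternal_band) == 2L,
            length(fetal_band) == 2L)
  structure(list(max_dev_frac = max_dev_frac,
                 maternal_band = maternal_band,
                 fetal_band = fetal_band),
            class = "quality_config")
}

band_for <- function(quality, role) {
  if (role == "maternal") quality$maternal_band else quality$fetal_band
}

window_passes <- function(tach, start_ms, end_ms, quality) {
  sel <- tach$time_ms > start_ms & tach$time_ms <= end_ms
  if (!any(sel)) return(FALSE)
  r <- tach$rri_ms[sel]
  band <- band_for(quality, tach$role)
  if (any(r < band[1L] | r > band[2L])) return(FALSE)
  med <- stats::median(r)
  all(abs(r - med) <= quality$max_dev_frac * med)
}

slice_tachogram <- function(tach, start_ms, end_ms) {
  sel <- tach$time_ms > start_ms & tach$time_ms <= end_ms
  rri_tachogram(tach$time_ms[sel], tach$rri_ms[sel],
                subject_id = tach$subject_id, role = tach$role)
}

#' Construct an analysis epoch
#'
#' An epoch is one artifact-free analysis window shared by both members of
#' a dyad: the maternal and fetal tachogram slices cover exactly the same
#' absolute time interval (the recordings are simultaneous on one clock).
#'
#' @param maternal,fetal [rri_tachogram] objects for the full recording.
#' @param start_ms,end_ms epoch bounds, ms.
#' @return object of class `rri_epoch` with elements `start_ms`, `end_ms`,
#'   `maternal`, `fetal` (tachogram slices restricted to the window).
#' @export
rri_epoch <- function(maternal, fetal, start_ms, end_ms) {
  stopifnot(inherits(maternal, "rri_tachogram"),
            inherits(fetal, "rri_tachogram"),
            end_ms > start_ms)
  structure(list(start_ms = start_ms, end_ms = end_ms,
                 maternal = slice_tachogram(maternal, start_ms, end_ms),
                 fetal = slice_tachogram(fetal, start_ms, end_ms)),
            class = "rri_epoch")
}

#' @export
print.rri_epoch <- function(x, ...) {
  cat(sprintf("<rri_epoch> [%.0f, %.0f] ms (%.0f s): %d maternal / %d fetal intervals\n",
              x$start_ms, x$end_ms, (x$end_ms - x$start_ms) / 1000,
              length(x$maternal$rri_ms), length(x$fetal$rri_ms)))
  invisible(x)
}

#' Select artifact-free epochs shared by a maternal-fetal dyad
#'
#' Discards the first minute of the recording, then slides a window of
#' `epoch_len_ms` in `step_ms` steps and keeps the earliest windows in which
#' BOTH subjects pass quality screening; after each accepted epoch the
#' search resumes at its end, so clean recordings yield consecutive epochs
#' while an artifact pushes the next epoch later. Returns up to `n_epochs`
#' epochs; if fewer clean windows exist the result carries
#' `attr(, "complete") = FALSE` so the caller can exclude the dyad
#' (recordings without at least two clean 3-minute epochs are conventionally
#' excluded).
#'
#' @param maternal,fetal full-recording [rri_tachogram]s on a shared clock.
#' @param epoch_len_ms epoch length, ms (default 180000 = 3 min).
#' @param n_epochs number of epochs sought (default 2).
#' @param quality a [quality_config()].
#' @param discard_ms initial segment to discard, ms (default 60000).
#' @param step_ms search-grid step, ms (default 1000).
#' @return list of [rri_epoch] with attribute `complete` (logical).
#' @export
select_epochs <- function(maternal, fetal, epoch_len_ms = 180000,
                          n_epochs = 2, quality = quality_config(),
                          discard_ms = 60000, step_ms = 1000) {
  stopifnot(inherits(maternal, "rri_tachogram"),
            inherits(fetal, "rri_tachogram"))
  rec_end <- min(max(maternal$time_ms), max(fetal$time_ms))
  if (rec_end < discard_ms + epoch_len_ms)
    stop("insufficient duration: record ends at ", round(rec_end),
         " ms but ", discard_ms + epoch_len_ms, " ms are needed")
  epochs <- list()
  from <- discard_ms
  while (length(epochs) < n_epochs) {
    starts <- seq(from, rec_end - epoch_len_ms, by = step_ms)
    hit <- NA
    for (s in starts) {
      if (window_passes(maternal, s, s + epoch_len_ms, quality) &&
          window_passes(fetal, s, s + epoch_len_ms, quality)) {
        hit <- s
        break
      }
    }
    if (is.na(hit)) break
    epochs[[length(epochs) + 1L]] <-
      rri_epoch(maternal, fetal, hit, hit + epoch_len_ms)
    from <- hit + epoch_len_ms
    if (from > rec_end - epoch_len_ms) break
  }
  attr(epochs, "complete") <- length(epochs) >= n_epochs
  epochs
}
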