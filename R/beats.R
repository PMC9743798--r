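#' Construct a beat series
#'
#' A beat series is the ordered sequence of R-peak times for one subject
#' within one recording, in milliseconds from recording start. It is the
#' elementary representation of a heartbeat record at 1 kHz timing
#' resolution.
#'
#' @param beat_ms numeric vector of beat times in ms, strictly increasing,
#'   all non-negative, at least two beats.
#' @param subject_id subject identifier.
#' @param role `"maternal"` or `"fetal"`.
#' @return an object of class `beat_series`: a list with elements
#'   `beat_ms`, `subject_id`, `role`.
#' @examples
#' b <- beat_series(c(0, 120, 240), "m1", "maternal")
#' length(b$beat_ms)
#' @export
beat_series <- function(beat_ms, subject_id = "subject", role = c("maternal", "fetal")) {
  role <- match.arg(role)
  beat_ms <- as.numeric(beat_ms)
  if (length(beat_ms) < 2L)
    stop("beat series needs at least 2 beats, got ", length(beat_ms))
  if (anyNA(beat_ms))
    stop("beat times contain NA")
  if (any(beat_ms < 0))
    stop("beat times must be >= 0")
  d <- diff(beat_ms)
  if (any(d <= 0)) {
    idx <- which(d <= 0)[1L] + 1L
    stop("beat times non-monotone at index ", idx)
  }
  structure(list(beat_ms = beat_ms, subject_id = subject_id, role = role),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s (%s): %d beats over %.1f s\n",
              x$subject_id, x$role, length(x$beat_ms),
              diff(range(x$beat_ms)) / 1000))
  invisible(x)
}

#' Construct an RR-interval tachogram
#'
#' The tachogram is the sequence of RR intervals (ms) indexed by the
#' occurrence time of each interval's terminating beat. It is irregularly
#' sampled by nature: one sample per heartbeat.
#'
#' @param time_ms terminating-beat times, ms, strictly increasing.
#' @param rri_ms interval durations, ms, all positive; same length as
#'   `time_ms`.
#' @param subject_id,role carried through from the beat series.
#' @return object of class `rri_tachogram`.
#' @export
rri_tachogram <- function(time_ms, rri_ms, subject_id = "subject",
                          role = c("maternal", "fetal")) {
  role <- match.arg(role)
  time_ms <- as.numeric(time_ms)
  rri_ms <- as.numeric(rri_ms)
  if (length(time_ms) != length(rri_ms))
    stop("time_ms and rri_ms must have equal length")
  if (any(rri_ms <= 0))
    stop("all RR intervals must be positive; first violation at index ",
         which(rri_ms <= 0)[1L])
  if (length(time_ms) > 1L && any(diff(time_ms) <= 0))
    stop("tachogram times non-monotone at index ",
         which(diff(time_ms) <= 0)[1L] + 1L)
  structure(list(time_ms = time_ms, rri_ms = rri_ms,
                 subject_id = subject_id, role = role),
            class = "rri_tachogram")
}

#' @export
print.rri_tachogram <- function(x, ...) {
  cat(sprintf("<rri_tachogram> %s (%s): %d intervals, mean RRI %.1f ms\n",
              x$subject_id, x$role, length(x$rri_ms), mean(x$rri_ms)))
  invisible(x)
}

#' Convert a beat series to an RR-interval tachogram
#'
#' `rri[i] = beat_ms[i+1] - beat_ms[i]`, stamped at the terminating beat,
#' so `time_ms = beat_ms[-1]`. The inverse operation (cumulative sum from
#' the first beat time) reproduces the beat series exactly.
#'
#' @param beats a [beat_series].
#' @return an [rri_tachogram].
#' @export
beats_to_rri <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_ms) < 2L)
    stop("insufficient data: need at least 2 beats to form an interval")
  rri_tachogram(time_ms = beats$beat_ms[-1L],
                rri_ms = diff(beats$beat_ms),
                subject_id = beats$subject_id, role = beats$role)
}

#' Read beat or RR-interval data from a delimited text file
#'
#' Accepts one subject per file, with either a `t_ms` column (beat times)
#' or an `rri_ms` column (successive intervals, converted to beat times by
#' cumulative summation from `start_ms`). A single unnamed numeric column
#' is also accepted and interpreted per `schema`. Values in seconds are
#' converted to ms on read; all internal times are milliseconds.
#'
#' @param path file path (CSV or TSV, sniffed from the extension).
#' @param schema `"beats"` (timestamps) or `"rri"` (interval durations).
#' @param units `"ms"` or `"s"`.
#' @param start_ms recording-start offset used for the `rri` schema.
#' @param subject_id,role passed to [beat_series()]; `subject_id` defaults
#'   to the file name without extension.
#' @return a [beat_series].
#' @export
read_beats <- function(path, schema = c("beats", "rri"), units = c("ms", "s"),
                       start_ms = 0, subject_id = NULL,
                       role = c("maternal", "fetal")) {
  schema <- match.arg(schema)
  units <- match.arg(units)
  role <- match.arg(role)
  if (!file.exists(path))
    stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "")
  col <- if (schema == "beats" && "t_ms" %in% names(dat)) "t_ms"
         else if (schema == "rri" && "rri_ms" %in% names(dat)) "rri_ms"
         else if (ncol(dat) == 1L) names(dat)[1L]
         else stop("cannot identify data column in ", path,
                   " (expected t_ms or rri_ms)")
  x <- as.numeric(dat[[col]])
  if (units == "s") x <- x * 1000
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (schema == "rri") {
    if (any(x <= 0))
      stop("non-positive RRI at index ", which(x <= 0)[1L])
    beat_ms <- start_ms + cumsum(c(0, x))
  } else {
    beat_ms <- x
  }
  beat_series(beat_ms, subject_id = subject_id, role = role)
}

#' Detect R peaks in a sampled ECG trace
#'
#' Simple amplitude-threshold peak picker intended for synthetic traces:
#' local maxima above an adaptive threshold (a configurable fraction of the
#' span between the trace mean and maximum), separated by at least a
#' refractory period. Not a clinical-grade QRS detector.
#'
#' @param ecg numeric vector, the sampled trace.
#' @param fs sampling rate, Hz (>= 100).
#' @param threshold_frac peak threshold as a fraction of `max - mean` above
#'   the mean; default 0.4.
#' @param refractory_ms minimum peak-to-peak separation, ms; default 50.
#' @param subject_id,role passed to [beat_series()].
#' @return a [beat_series] of detected peak times.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.4, refractory_ms = 50,
                           subject_id = "detected",
                           role = c("maternal", "fetal")) {
  role <- match.arg(role)
  if (fs < 100)
    stop("sampling rate must be >= 100 Hz")
  n <- length(ecg)
  if (n < 2 * fs)
    stop("trace shorter than 2 s")
  thr <- mean(ecg) + threshold_frac * (max(ecg) - mean(ecg))
  if (max(ecg) <= mean(ecg) || !is.finite(thr))
    stop("no peaks found: trace has no excursion above its mean")
  # pad ends so a peak at the first or last sample is still a local max
  padded <- c(-Inf, ecg, -Inf)
  core <- padded[2:(n + 1L)]
  is_peak <- core > padded[1:n] & core >= padded[3:(n + 2L)] & core > thr
  cand <- which(is_peak)
  if (length(cand) == 0L)
    stop("no peaks found above threshold")
  refr <- refractory_ms / 1000 * fs
  keep <- cand[1L]
  if (length(cand) > 1L) {
    for (i in cand[-1L]) {
      last <- keep[length(keep)]
      if (i - last >= refr) {
        keep <- c(keep, i)
      } else if (ecg[i] > ecg[last]) {
        keep[length(keep)] <- i  # taller peak inside refractory window wins
      }
    }
  }
  if (length(keep) < 2L)
    stop("no peaks found: fewer than 2 peaks detected")
  beat_series((keep - 1L) / fs * 1000, subject_id = subject_id, role = role)
}
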