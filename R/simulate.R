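#' Parameters of a simulated maternal-fetal dyad
#'
#' The generator mimics what the similarity analysis needs from a real
#' recording: a maternal RR-interval process with slow LF/HF oscillations
#' plus autoregressive noise, and a fetal process whose fluctuations are a
#' mixture of a component coupled to the maternal fluctuation (strength
#' `coupling_rho`, sign `coupling_sign`) and an independent slow component.
#' The two variance shares are `rho^2` and `1 - rho^2` of the fetal
#' fluctuation variance, so that the expected correlation between the
#' maternal and fetal fluctuations is approximately `rho` (exactly `rho`
#' before resampling; per-bin averaging attenuates the fast components of
#' both processes similarly). Beat times are obtained by integrating the
#' instantaneous RRI and quantizing to 1 ms, the timing granularity of a
#' 1 kHz acquisition.
#'
#' @param maternal_mean_rri maternal mean RRI, ms (default 130, a typical
#'   value for an anesthetized adult mouse; exposed as a parameter, not a
#'   measured fact).
#' @param fetal_mean_rri fetal mean RRI, ms. `NULL` (default) draws
#'   uniformly from 306-981 ms, the observed range of mean fetal RRI in
#'   anesthetized pregnant mice.
#' @param coupling_rho coupling strength in `[0, 1]`.
#' @param coupling_sign `+1` (fetal RRI moves with maternal RRI) or `-1`
#'   (against it).
#' @param lf_freq,hf_freq maternal oscillation frequencies, Hz (defaults
#'   0.08 and 0.2, inside the LF and HF coherence bands).
#' @param maternal_osc_amp amplitude of the maternal LF oscillation, ms;
#'   the HF component has half this amplitude.
#' @param maternal_noise_sd stationary sd of the maternal AR(1) noise, ms.
#' @param fetal_noise_sd overall fetal fluctuation scale, ms: the coupled
#'   and independent parts have sds `rho * fetal_noise_sd` and
#'   `sqrt(1 - rho^2) * fetal_noise_sd`.
#' @param maternal_ar,fetal_ar AR(1) coefficients of the noise processes on
#'   a 100-ms grid. The fetal value (0.98, correlation time ~5 s) keeps the
#'   independent fetal variability slow enough to survive 2-s resampling,
#'   as the coupled oscillations do.
#' @param duration_s recording length, s (default 900 = 15 min).
#' @param lag_ms delay of the fetal coupled component behind the maternal
#'   fluctuation, ms (default 0: instantaneous shared modulation, matching
#'   the zero-lag similarity statistic).
#' @param coupling_drift_sd sd of a slow drift of the effective coupling
#'   gain around `coupling_rho` (correlation time ~150 s, truncated to
#'   `[0, 1]`). Default 0: constant coupling, so the calibration
#'   `rho ~ expected correlation` holds exactly. Cohort scenarios enable a
#'   nonzero drift to emulate the nonstationarity of real recordings, where
#'   successive epochs of one dyad can score very differently.
#' @param seed integer seed; identical seeds give identical dyads.
#' @return a list of class `dyad_params`.
#' @export
dyad_params <- function(maternal_mean_rri = 130, fetal_mean_rri = NULL,
                        coupling_rho = 0.5, coupling_sign = 1,
                        lf_freq = 0.08, hf_freq = 0.2,
                        maternal_osc_amp = 8, maternal_noise_sd = 2,
                        fetal_noise_sd = 25,
                        maternal_ar = 0.9, fetal_ar = 0.98,
                        duration_s = 900, lag_ms = 0,
                        coupling_drift_sd = 0, seed = NULL) {
  stopifnot(maternal_mean_rri > 0,
            coupling_rho >= 0, coupling_rho <= 1,
            coupling_sign %in% c(-1, 1),
            duration_s > 0)
  if (!is.null(fetal_mean_rri) &&
      (fetal_mean_rri <= 200 || fetal_mean_rri >= 1100))
    stop("fetal_mean_rri must lie in (200, 1100) ms")
  structure(list(maternal_mean_rri = maternal_mean_rri,
                 fetal_mean_rri = fetal_mean_rri,
                 coupling_rho = coupling_rho, coupling_sign = coupling_sign,
                 lf_freq = lf_freq, hf_freq = hf_freq,
                 maternal_osc_amp = maternal_osc_amp,
                 maternal_noise_sd = maternal_noise_sd,
                 fetal_noise_sd = fetal_noise_sd,
                 maternal_ar = maternal_ar, fetal_ar = fetal_ar,
                 duration_s = duration_s, lag_ms = lag_ms,
                 coupling_drift_sd = coupling_drift_sd, seed = seed),
            class = "dyad_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# stationary AR(1) sample of length n with sd `sd` and coefficient `phi`
ar1_noise <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# maternal fluctuation (ms, zero-mean) on a dt-s grid covering duration_s
maternal_fluctuation <- function(params, dt = 0.1, margin_s = 10) {
  n <- ceiling((params$duration_s + margin_s) / dt)
  tg <- (seq_len(n) - 1L) * dt
  phase <- stats::runif(1, 0, 2 * pi)
  osc <- params$maternal_osc_amp *
    (sin(2 * pi * params$lf_freq * tg) +
       0.5 * sin(2 * pi * params$hf_freq * tg + phase))
  osc + ar1_noise(n, params$maternal_ar, params$maternal_noise_sd)
}

# integrate an instantaneous-RRI trajectory into 1 ms-quantized beat times
integrate_beats <- function(mean_rri, fluct, dt, duration_s) {
  n_max <- ceiling(duration_s * 1000 / (0.09 * mean_rri)) + 2L
  beats <- numeric(n_max)
  clip <- 0.1 * mean_rri
  n_clipped <- 0L
  t <- 0
  i <- 1L
  ng <- length(fluct)
  interp <- function(tt) {
    pos <- tt / dt
    i0 <- min(floor(pos) + 1L, ng - 1L)
    w <- pos - (i0 - 1L)
    (1 - w) * fluct[i0] + w * fluct[i0 + 1L]
  }
  while (t < duration_s) {
    i <- i + 1L
    # the interval length reflects the modulation accumulated over the
    # interval: evaluate the fluctuation at the interval midpoint
    # (second-order approximation of the interval average)
    rri0 <- max(mean_rri + interp(t), clip)
    rri <- mean_rri + interp(t + rri0 / 2000)
    if (rri < clip) {
      rri <- clip
      n_clipped <- n_clipped + 1L
    }
    t <- t + rri / 1000
    beats[i] <- t
  }
  if (n_clipped > 0L)
    warning(n_clipped, " instantaneous RRI value(s) clipped at 10% of mean")
  round(beats[seq_len(i)] * 1000)
}

#' Simulate one maternal-fetal dyad
#'
#' Generates simultaneous maternal and fetal beat series with known
#' coupling strength and sign; see [dyad_params()] for the model. The same
#' seed always yields identical beat series.
#'
#' @param params a [dyad_params()].
#' @return list with `maternal` and `fetal` ([beat_series]), the realized
#'   `fetal_mean_rri`, and `params`.
#' @export
simulate_dyad <- function(params = dyad_params()) {
  stopifnot(inherits(params, "dyad_params"))
  with_seed(params$seed, {
    dt <- 0.1
    fluct_m <- maternal_fluctuation(params, dt = dt)
    mother <- beat_series(integrate_beats(params$maternal_mean_rri, fluct_m,
                                          dt, params$duration_s),
                          subject_id = "m", role = "maternal")
    fet <- simulate_fetus(fluct_m, params, dt = dt)
    list(maternal = mother, fetal = fet$beats,
         fetal_mean_rri = fet$fetal_mean_rri, params = params)
  })
}

# fetal half of a dyad, coupled to a given maternal fluctuation grid
simulate_fetus <- function(fluct_m, params, dt = 0.1, subject_id = "f") {
  f_mean <- params$fetal_mean_rri
  if (is.null(f_mean)) f_mean <- stats::runif(1, 306, 981)
  rho <- params$coupling_rho
  sd_m <- stats::sd(fluct_m)
  g <- if (sd_m > 0) params$fetal_noise_sd / sd_m else 0
  lag_steps <- round(params$lag_ms / 1000 / dt)
  coupled <- if (lag_steps > 0) {
    c(numeric(lag_steps), fluct_m[seq_len(length(fluct_m) - lag_steps)])
  } else {
    fluct_m
  }
  gain <- rho
  if (params$coupling_drift_sd > 0) {
    # slow wander of the effective coupling gain (correlation time ~150 s)
    drift <- ar1_noise(length(fluct_m), exp(-dt / 150),
                       params$coupling_drift_sd)
    gain <- pmin(1, pmax(0, rho + drift))
  }
  fluct_f <- params$coupling_sign * gain * g * coupled +
    ar1_noise(length(fluct_m), params$fetal_ar,
              sqrt(1 - rho^2) * params$fetal_noise_sd)
  beats <- beat_series(integrate_beats(f_mean, fluct_f, dt,
                                       params$duration_s),
                       subject_id = subject_id, role = "fetal")
  list(beats = beats, fetal_mean_rri = f_mean)
}

#' Cohort simulation scenario
#'
#' Two designs are provided. `"development"` draws dyads at embryonic days
#' 13.5, 15.5, 17.5 and 18.5 with a coupling schedule increasing with age
#' (default 0.2/0.4/0.6/0.8), and sample sizes mirroring the typical-
#' development cohort (6/6/10/7 mothers carrying 10/10/17/11 analyzed
#' fetuses). `"asd"` draws a saline and a VPA arm at ED15.5 and ED18.5
#' (8+8 mothers with 13+13 fetuses at ED15.5; 5+5 mothers with 7+7 fetuses
#' at ED18.5); the VPA arm's coupling is the saline schedule multiplied by
#' `vpa_multiplier` (default 0.3 and 0.95) — well below 1 at ED15.5 and close to 1 at ED18.5,
#' emulating delayed but eventually catching-up development.
#'
#' @param name `"development"` or `"asd"`.
#' @param eds embryonic days simulated.
#' @param mothers,fetuses per-ED counts (for `"asd"`, per arm).
#' @param rho_schedule coupling strength per ED (saline/typical arm).
#' @param vpa_multiplier per-ED multiplier applied to `rho_schedule` for
#'   the VPA arm (`"asd"` only).
#' @param coupling_sign coupling sign given to every dyad.
#' @param coupling_drift_sd within-recording drift of the effective
#'   coupling gain handed to every dyad (see [dyad_params()]); real
#'   similarity scores vary markedly between successive epochs of one
#'   dyad, so the cohort default is 0.15 rather than the dyad generator's
#'   constant-coupling 0.
#' @param rho_jitter_sd sd of the per-dyad Gaussian jitter added to the
#'   scheduled coupling strength (truncated to `[0, 1]`). Real cohorts show
#'   a wide within-stage spread of similarity coefficients — individual
#'   dyads at one stage can range from weakly to almost perfectly coupled —
#'   so dyad-level heterogeneity is part of the emulated conditions
#'   (default 0.15).
#' @param dyad base [dyad_params()] shared by all dyads (its `coupling_rho`,
#'   `coupling_sign` and `seed` are overridden per dyad).
#' @return a list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(name = c("development", "asd"),
                            eds = NULL, mothers = NULL, fetuses = NULL,
                            rho_schedule = NULL, vpa_multiplier = NULL,
                            coupling_sign = 1, rho_jitter_sd = 0.15,
                            coupling_drift_sd = 0.15,
                            dyad = dyad_params()) {
  name <- match.arg(name)
  if (name == "development") {
    if (is.null(eds)) eds <- c(13.5, 15.5, 17.5, 18.5)
    if (is.null(mothers)) mothers <- c(6, 6, 10, 7)
    if (is.null(fetuses)) fetuses <- c(10, 10, 17, 11)
    if (is.null(rho_schedule)) rho_schedule <- c(0.2, 0.4, 0.6, 0.8)
  } else {
    if (is.null(eds)) eds <- c(15.5, 18.5)
    if (is.null(mothers)) mothers <- c(8, 5)
    if (is.null(fetuses)) fetuses <- c(13, 7)
    if (is.null(rho_schedule)) rho_schedule <- c(0.4, 0.8)
    if (is.null(vpa_multiplier)) vpa_multiplier <- c(0.3, 0.95)
  }
  stopifnot(length(mothers) == length(eds),
            length(fetuses) == length(eds),
            length(rho_schedule) == length(eds),
            all(mothers >= 1), all(fetuses >= mothers),
            all(rho_schedule >= 0 & rho_schedule <= 1))
  stopifnot(rho_jitter_sd >= 0)
  structure(list(name = name, eds = eds, mothers = mothers,
                 fetuses = fetuses, rho_schedule = rho_schedule,
                 vpa_multiplier = vpa_multiplier,
                 coupling_sign = coupling_sign,
                 rho_jitter_sd = rho_jitter_sd,
                 coupling_drift_sd = coupling_drift_sd, dyad = dyad),
            class = "cohort_scenario")
}

# split n_fetuses over n_mothers: 2 per mother where possible, remainder 1
allocate_fetuses <- function(n_mothers, n_fetuses) {
  per <- rep(n_fetuses %/% n_mothers, n_mothers)
  extra <- n_fetuses %% n_mothers
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  per
}

#' Simulate a cohort of dyads
#'
#' Draws every dyad of the scenario: one maternal recording per mother,
#' with that mother's fetuses coupled to the same maternal fluctuation
#' (fetuses sharing a mother therefore share their maternal series, as in
#' a real simultaneous recording). If `outdir` is given, per-subject beat
#' CSVs (`t_ms` column) and a `manifest.csv` are written there and file
#' paths appear in the manifest; the same `seed` always produces
#' byte-identical files.
#'
#' @param scenario a [cohort_scenario()].
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param outdir optional output directory.
#' @param overwrite allow writing into an existing `outdir`.
#' @return list of class `mf_cohort` with `manifest` (data.frame:
#'   `mother_id, fetus_id, ed, group, rho, maternal_file, fetal_file`) and
#'   `dyads` (named list of `list(maternal, fetal)` beat series, keyed by
#'   `fetus_id`).
#' @export
simulate_cohort <- function(scenario = cohort_scenario(), seed = 1,
                            outdir = NULL, overwrite = FALSE) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && length(dir(outdir)) > 0 && !overwrite)
      stop("output directory ", outdir,
           " exists and is not empty; set overwrite = TRUE")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  }
  groups <- if (scenario$name == "development") "development"
            else c("saline", "vpa")
  rows <- list()
  dyads <- list()
  counter <- 0L
  for (gi in seq_along(groups)) {
    group <- groups[gi]
    for (ei in seq_along(scenario$eds)) {
      ed <- scenario$eds[ei]
      rho <- scenario$rho_schedule[ei]
      if (group == "vpa") rho <- rho * scenario$vpa_multiplier[ei]
      per <- allocate_fetuses(scenario$mothers[ei], scenario$fetuses[ei])
      for (mi in seq_len(scenario$mothers[ei])) {
        counter <- counter + 1L
        mother_id <- sprintf("%s_ed%s_m%02d", group, ed, mi)
        mseed <- (seed * 10007L + counter * 101L) %% .Machine$integer.max
        base <- scenario$dyad
        base$coupling_rho <- rho
        base$coupling_sign <- scenario$coupling_sign
        base$coupling_drift_sd <- scenario$coupling_drift_sd
        maternal <- with_seed(mseed, {
          fl <- maternal_fluctuation(base)
          list(fluct = fl,
               beats = beat_series(
                 integrate_beats(base$maternal_mean_rri, fl, 0.1,
                                 base$duration_s),
                 subject_id = mother_id, role = "maternal"))
        })
        for (fi in seq_len(per[mi])) {
          counter <- counter + 1L
          fetus_id <- sprintf("%s_f%d", mother_id, fi)
          fseed <- (seed * 10007L + counter * 101L) %% .Machine$integer.max
          fet <- with_seed(fseed, {
            fbase <- base
            fbase$coupling_rho <- min(1, max(0, rho +
              stats::rnorm(1, 0, scenario$rho_jitter_sd)))
            c(simulate_fetus(maternal$fluct, fbase, subject_id = fetus_id),
              list(rho_dyad = fbase$coupling_rho))
          })
          dyads[[fetus_id]] <- list(maternal = maternal$beats,
                                    fetal = fet$beats)
          mfile <- ffile <- NA_character_
          if (!is.null(outdir)) {
            mfile <- file.path(outdir, paste0(mother_id, ".csv"))
            ffile <- file.path(outdir, paste0(fetus_id, ".csv"))
            if (!file.exists(mfile))
              utils::write.csv(data.frame(t_ms = maternal$beats$beat_ms),
                               mfile, row.names = FALSE)
            utils::write.csv(data.frame(t_ms = fet$beats$beat_ms),
                             ffile, row.names = FALSE)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            mother_id = mother_id, fetus_id = fetus_id, ed = ed,
            group = group, rho = rho, rho_dyad = fet$rho_dyad,
            maternal_file = mfile, fetal_file = ffile,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    # store file names relative to the manifest so the tree is relocatable
    # and identical seeds give byte-identical output
    disk <- manifest
    disk$maternal_file <- basename(disk$maternal_file)
    disk$fetal_file <- basename(disk$fetal_file)
    utils::write.csv(disk, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, dyads = dyads, scenario = scenario,
                 seed = seed),
            class = "mf_cohort")
}

#' @export
print.mf_cohort <- function(x, ...) {
  cat(sprintf("<mf_cohort> '%s': %d dyads (%d mothers), seed %d\n",
              x$scenario$name, nrow(x$manifest),
              length(unique(x$manifest$mother_id)), x$seed))
  print(table(ed = x$manifest$ed, group = x$manifest$group))
  invisible(x)
}

#' Synthesize a toy ECG trace from beat times
#'
#' Places a Gaussian R-wave bump (sd `width_ms`) of unit amplitude at each
#' beat time over Gaussian baseline noise. Intended to exercise
#' [detect_r_peaks()] in round-trip tests, not to model ECG morphology.
#'
#' @param beats a [beat_series].
#' @param fs sampling rate, Hz (default 1000).
#' @param width_ms Gaussian sd of the R bump, ms.
#' @param noise_sd baseline noise sd as a fraction of peak amplitude.
#' @param pad_ms trailing padding after the last beat, ms.
#' @return list with `t_s` (sample times, s) and `x` (trace).
#' @export
synth_ecg <- function(beats, fs = 1000, width_ms = 5, noise_sd = 0.02,
                      pad_ms = 200) {
  stopifnot(inherits(beats, "beat_series"), fs > 0)
  n <- ceiling((max(beats$beat_ms) + pad_ms) / 1000 * fs) + 1L
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  sd_samp <- width_ms / 1000 * fs
  half <- ceiling(5 * sd_samp)
  for (b in beats$beat_ms) {
    c0 <- round(b / 1000 * fs) + 1L
    idx <- max(1L, c0 - half):min(n, c0 + half)
    x[idx] <- x[idx] + exp(-((idx - c0)^2) / (2 * sd_samp^2))
  }
  list(t_s = (seq_len(n) - 1L) / fs, x = x)
}
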