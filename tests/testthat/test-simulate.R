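test_that("dyad simulation is deterministic under a fixed seed", {
  p <- dyad_params(coupling_rho = 0.6, duration_s = 120, seed = 41)
  d1 <- simulate_dyad(p)
  d2 <- simulate_dyad(p)
  expect_identical(d1$maternal$beat_ms, d2$maternal$beat_ms)
  expect_identical(d1$fetal$beat_ms, d2$fetal$beat_ms)
  d3 <- simulate_dyad(dyad_params(coupling_rho = 0.6, duration_s = 120,
                                  seed = 42))
  expect_false(identical(d1$fetal$beat_ms, d3$fetal$beat_ms))
})

test_that("generated series respect timing and amplitude contracts", {
  d <- simulate_dyad(dyad_params(duration_s = 900, seed = 43))
  for (b in list(d$maternal, d$fetal)) {
    expect_true(all(diff(b$beat_ms) > 0))
    expect_true(all(b$beat_ms == round(b$beat_ms)))  # 1 ms quantization
  }
  # realized mean fetal RRI within 2% of the drawn parameter
  rri <- diff(d$fetal$beat_ms)
  expect_lt(abs(mean(rri) - d$fetal_mean_rri) / d$fetal_mean_rri, 0.02)
  expect_gt(d$fetal_mean_rri, 306 - 1e-9)
  expect_lt(d$fetal_mean_rri, 981 + 1e-9)
  mrri <- diff(d$maternal$beat_ms)
  expect_lt(abs(mean(mrri) - 130) / 130, 0.02)
})

test_that("extreme parameters clip the instantaneous RRI with a warning", {
  p <- dyad_params(maternal_mean_rri = 130, maternal_osc_amp = 200,
                   duration_s = 60, seed = 44, fetal_mean_rri = 600)
  expect_warning(d <- simulate_dyad(p), "clipped")
  expect_true(all(diff(d$maternal$beat_ms) >= 13 - 1e-9))
})

test_that("maternal spectral content peaks at the configured frequencies", {
  d <- simulate_dyad(dyad_params(duration_s = 900, seed = 45,
                                 fetal_mean_rri = 600))
  tach <- beats_to_rri(d$maternal)
  u <- resample_uniform(tach, 60000, 780000)  # 360 samples at 0.5 Hz
  sp <- stats::spec.pgram(stats::ts(u$values, frequency = 0.5),
                          spans = 3, plot = FALSE, detrend = TRUE)
  df <- sp$freq[2] - sp$freq[1]
  near <- function(f0) {
    sel <- abs(sp$freq - f0) <= 0.025
    sp$freq[sel][which.max(sp$spec[sel])]
  }
  expect_lte(abs(near(0.08) - 0.08), df + 1e-9)
  expect_lte(abs(near(0.2) - 0.2), df + 1e-9)
})

test_that("coupling strength and sign propagate to the scores", {
  fit_pos <- score_dyad(rho = 1, seed = 46)
  expect_gte(fit_pos$cc2, 0.95)
  expect_gte(fit_pos$cc1, 0.95)
  fit_neg <- score_dyad(rho = 1, seed = 46, sign = -1)
  expect_lte(fit_neg$cc2, -0.95)
  expect_gte(fit_neg$cc1, 0.95)
  # same maternal seed, opposite sign: mirror image
  expect_equal(fit_neg$cc1, fit_pos$cc1, tolerance = 0.02)
})

test_that("decoupled dyads score near the independent-pair null", {
  set.seed(47)
  v <- vapply(1:30, function(k) coef(score_dyad(rho = 0, seed = 400 + k)),
              numeric(4))
  # null CC1 for 10-sample windows is ~E|r| of unrelated smooth series;
  # must sit well below weak-coupling scores and CC2 near zero
  expect_lt(mean(v["cc1", ]), 0.45)
  expect_lt(abs(mean(v["cc2", ])), 0.15)
  expect_lt(mean(v["clf", ]), 0.45)
})

test_that("cohort simulation writes a deterministic, complete file tree", {
  sc <- cohort_scenario("development", mothers = c(2, 2), fetuses = c(3, 3),
                        eds = c(13.5, 18.5), rho_schedule = c(0.2, 0.8),
                        dyad = dyad_params(duration_s = 300))
  tmp1 <- withr::local_tempdir()
  tmp2 <- withr::local_tempdir()
  co1 <- simulate_cohort(sc, seed = 5, outdir = tmp1)
  co2 <- simulate_cohort(sc, seed = 5, outdir = tmp2)
  expect_equal(nrow(co1$manifest), 6)
  expect_setequal(unique(co1$manifest$ed), c(13.5, 18.5))
  files1 <- sort(dir(tmp1))
  expect_identical(files1, sort(dir(tmp2)))
  expect_true("manifest.csv" %in% files1)
  for (fn in files1) {
    expect_identical(readBin(file.path(tmp1, fn), "raw", 1e6),
                     readBin(file.path(tmp2, fn), "raw", 1e6))
  }
  # different seed -> different beats
  co3 <- simulate_cohort(sc, seed = 6)
  expect_false(identical(co1$dyads[[1]]$fetal$beat_ms,
                         co3$dyads[[1]]$fetal$beat_ms))
  # refuse to clobber without overwrite
  expect_error(simulate_cohort(sc, seed = 5, outdir = tmp1), "overwrite")
  expect_silent(simulate_cohort(sc, seed = 5, outdir = tmp1,
                                overwrite = TRUE))
})

test_that("default scenarios mirror the studied sample sizes", {
  dev <- cohort_scenario("development")
  expect_equal(dev$mothers, c(6, 6, 10, 7))
  expect_equal(dev$fetuses, c(10, 10, 17, 11))
  expect_equal(dev$rho_schedule, c(0.2, 0.4, 0.6, 0.8))
  asd <- cohort_scenario("asd")
  expect_equal(asd$eds, c(15.5, 18.5))
  expect_equal(asd$mothers, c(8, 5))
  expect_equal(asd$fetuses, c(13, 7))
  expect_true(all(asd$vpa_multiplier < 1))
  expect_gt(asd$vpa_multiplier[2], asd$vpa_multiplier[1])
})

test_that("synthetic ECG places unit bumps at the beat times", {
  b <- beat_series(c(100, 220, 400))
  tr <- synth_ecg(b, fs = 1000, noise_sd = 0)
  peaks <- which(diff(sign(diff(tr$x))) == -2) + 1
  peaks <- peaks[tr$x[peaks] > 0.5]
  expect_length(peaks, 3)
  expect_equal((peaks - 1), c(100, 220, 400))
  # round trip through the detector at +/- 1 ms
  set.seed(48)
  d <- simulate_dyad(dyad_params(duration_s = 20, seed = 48,
                                 fetal_mean_rri = 500))
  tr2 <- synth_ecg(d$fetal, fs = 1000)
  det <- detect_r_peaks(tr2$x, fs = 1000)
  expect_equal(length(det$beat_ms), length(d$fetal$beat_ms))
  expect_true(all(abs(det$beat_ms - d$fetal$beat_ms) <= 1))
})
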