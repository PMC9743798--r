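test_that("beat series validate their invariants", {
  b <- beat_series(c(0, 120, 240))
  expect_length(b$beat_ms, 3)
  expect_error(beat_series(c(0, 120, 100)), "non-monotone at index 3")
  expect_error(beat_series(c(0)), "at least 2 beats")
  expect_error(beat_series(c(-5, 100)), ">= 0")
})

test_that("read_beats handles beat and RRI schemas, units and errors", {
  tmp <- withr::local_tempdir()
  bfile <- file.path(tmp, "beats.csv")
  write.csv(data.frame(t_ms = c(0, 120, 240)), bfile, row.names = FALSE)
  b <- read_beats(bfile)
  expect_equal(b$beat_ms, c(0, 120, 240))

  rfile <- file.path(tmp, "rri.csv")
  write.csv(data.frame(rri_ms = c(120, 120)), rfile, row.names = FALSE)
  r <- read_beats(rfile, schema = "rri")
  expect_equal(r$beat_ms, c(0, 120, 240))
  r2 <- read_beats(rfile, schema = "rri", start_ms = 500)
  expect_equal(r2$beat_ms, c(500, 620, 740))

  sfile <- file.path(tmp, "sec.csv")
  write.csv(data.frame(t_ms = c(0, 0.12, 0.24)), sfile, row.names = FALSE)
  expect_equal(read_beats(sfile, units = "s")$beat_ms, c(0, 120, 240))

  bad <- file.path(tmp, "bad.csv")
  write.csv(data.frame(t_ms = c(0, 120, 100)), bad, row.names = FALSE)
  expect_error(read_beats(bad), "non-monotone at index 3")
  badr <- file.path(tmp, "badr.csv")
  write.csv(data.frame(rri_ms = c(120, -5)), badr, row.names = FALSE)
  expect_error(read_beats(badr, schema = "rri"), "non-positive RRI at index 2")
  expect_error(read_beats(file.path(tmp, "nope.csv")), "not found")
})

test_that("beats_to_rri takes first differences and round-trips", {
  tach <- beats_to_rri(beat_series(c(0, 120, 250)))
  expect_equal(tach$rri_ms, c(120, 130))
  expect_equal(tach$time_ms, c(120, 250))
  # a single interval at the largest plausible fetal scale
  expect_equal(beats_to_rri(beat_series(c(0, 928)))$rri_ms, 928)
  # 1200 equally spaced beats spanning 180 s -> 1199 intervals
  tach3 <- beats_to_rri(beat_series(seq(0, 180000 - 150, by = 150)))
  expect_length(tach3$rri_ms, 1199)
  expect_true(all(tach3$rri_ms == 150))
  # round trip: cumulative sum of rri reproduces beat times
  b <- beat_series(c(10, 140, 300, 420))
  t2 <- beats_to_rri(b)
  expect_equal(c(b$beat_ms[1], b$beat_ms[1] + cumsum(t2$rri_ms)), b$beat_ms)
})

test_that("epoch selection discards the first minute and prefers consecutive windows", {
  m <- regular_tach(130, 900, "maternal")
  f <- regular_tach(600, 900, "fetal", id = "f")
  eps <- select_epochs(m, f)
  expect_length(eps, 2)
  expect_true(attr(eps, "complete"))
  expect_equal(eps[[1]]$start_ms, 60000)
  expect_equal(eps[[1]]$end_ms, 240000)
  expect_equal(eps[[2]]$start_ms, 240000)  # consecutive
  for (ep in eps) {
    expect_equal(ep$end_ms - ep$start_ms, 180000)
    expect_true(ep$start_ms >= 60000)
    # identical absolute bounds for both subjects
    expect_true(all(ep$maternal$time_ms > ep$start_ms &
                      ep$maternal$time_ms <= ep$end_ms))
    expect_true(all(ep$fetal$time_ms > ep$start_ms &
                      ep$fetal$time_ms <= ep$end_ms))
  }
})

test_that("an ectopic spike pushes the first epoch past it", {
  m <- regular_tach(130, 900, "maternal")
  f <- regular_tach(600, 900, "fetal", id = "f")
  # ectopic beat in minute 2-3 of the fetal record: one huge interval
  f$rri_ms[f$time_ms > 150000 & f$time_ms <= 150600] <- 1500
  eps <- select_epochs(m, f)
  expect_true(eps[[1]]$start_ms >= 150600)
  expect_true(attr(eps, "complete"))
})

test_that("records too short for one epoch are rejected", {
  m <- regular_tach(130, 120, "maternal")
  f <- regular_tach(600, 120, "fetal", id = "f")
  expect_error(select_epochs(m, f), "insufficient duration")
})

test_that("incomplete dyads are flagged rather than dropped", {
  m <- regular_tach(130, 300, "maternal")  # room for exactly one epoch
  f <- regular_tach(600, 300, "fetal", id = "f")
  eps <- select_epochs(m, f)
  expect_length(eps, 1)
  expect_false(attr(eps, "complete"))
})

test_that("R-peak detection recovers synthetic beats to sample precision", {
  set.seed(71)
  d <- simulate_dyad(dyad_params(duration_s = 30, seed = 71,
                                 fetal_mean_rri = 600))
  ecg <- synth_ecg(d$fetal, fs = 1000)
  det <- detect_r_peaks(ecg$x, fs = 1000, role = "fetal")
  truth <- d$fetal$beat_ms
  # >= 99% of true beats recovered within +/- 1 ms (1 sample at 1 kHz)
  hit <- vapply(truth, function(b) any(abs(det$beat_ms - b) <= 1),
                logical(1))
  expect_gte(mean(hit), 0.99)
  expect_lte(abs(length(det$beat_ms) - length(truth)), 1)
})

test_that("degenerate traces are rejected by the peak detector", {
  expect_error(detect_r_peaks(numeric(5000), fs = 1000), "no peaks")
  expect_error(detect_r_peaks(rep(1, 5000), fs = 1000), "no peaks")
  expect_error(detect_r_peaks(rnorm(150), fs = 100), "shorter than 2 s")
  # two clean Gaussian bumps 120 ms apart -> exactly 2 beats
  b2 <- beat_series(c(1000, 1120))
  tr <- synth_ecg(b2, fs = 1000, noise_sd = 0, pad_ms = 1000)
  det <- detect_r_peaks(tr$x, fs = 1000)
  expect_length(det$beat_ms, 2)
  expect_equal(det$beat_ms, c(1000, 1120), tolerance = 1e-9)
})
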