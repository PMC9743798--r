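# shared fixtures, all generated in code

# tachogram with equally spaced beats: one beat every `rri` ms for `dur_s` s
regular_tach <- function(rri, dur_s = 300, role = "maternal",
                         id = "reg") {
  beats_to_rri(beat_series(seq(0, dur_s * 1000, by = rri),
                           subject_id = id, role = role))
}

# simulate one dyad and score its first clean 3-min epoch directly
score_dyad <- function(rho, seed, sign = 1, duration_s = 300,
                       fetal_mean_rri = NULL, ...) {
  d <- simulate_dyad(dyad_params(coupling_rho = rho, coupling_sign = sign,
                                 duration_s = duration_s,
                                 fetal_mean_rri = fetal_mean_rri,
                                 seed = seed, ...))
  ep <- rri_epoch(beats_to_rri(d$maternal), beats_to_rri(d$fetal),
                  60000, 240000)
  score_epoch(ep)
}

# pair of random normalized 90-sample series
random_norm_pair <- function(n = 90) {
  list(m = normalize_series(rnorm(n)), f = normalize_series(rnorm(n)))
}

# direct evaluation of the zero-lag windowed CC definition, element by
# element, as an oracle independent of the vectorized implementation
brute_force_wcc <- function(m, f, window_len = 10) {
  n_win <- length(m) %/% window_len
  out <- numeric(n_win)
  for (w in seq_len(n_win)) {
    num <- 0
    em <- 0
    ef <- 0
    for (k in seq_len(window_len)) {
      i <- (w - 1) * window_len + k
      num <- num + m[i] * f[i]
      em <- em + m[i]^2
      ef <- ef + f[i]^2
    }
    out[w] <- num / sqrt(em * ef)
  }
  out
}
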