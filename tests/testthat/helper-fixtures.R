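# Small, fast fixtures shared across test files. 200 Hz keeps wavelet FFTs
# cheap while leaving the 60 Hz top of the fA grid well below Nyquist.
fast_spec <- function(...) paradigm_spec(sampling_rate_hz = 200, ...)

quiet_noise <- function(...) noise_spec(noise_sd = 0, assr_amplitude = 0, ...)

# ensemble of pure 1/f noise trials, no oscillatory components
noise_ensemble <- function(n_trials, spec = fast_spec(), seed = 1,
                           exponent = 1) {
  nt <- round(diff(spec$epoch_window_s) * spec$sampling_rate_hz) + 1
  set.seed(seed)
  d <- t(replicate(n_trials,
                   one_over_f_noise(nt, spec$sampling_rate_hz, exponent, 1)))
  trial_ensemble(d, seq(spec$epoch_window_s[1], spec$epoch_window_s[2],
                        by = 1 / spec$sampling_rate_hz),
                 spec$sampling_rate_hz)
}

# brute-force across-trials MVL: per-sample complex mean, then time average
mvl_oracle <- function(phase, amp) {
  vals <- vapply(seq_len(ncol(phase)), function(j) {
    v <- 0 + 0i
    for (t in seq_len(nrow(phase)))
      v <- v + amp[t, j] * exp(1i * phase[t, j])
    Mod(v / nrow(phase))
  }, 1)
  mean(vals)
}

# exact sign-flip null of max cluster mass (enumeration oracle)
enumerate_null <- function(D, nr, nc, t_crit, adjacency = "4") {
  n <- nrow(D)
  apply(expand.grid(rep(list(c(-1, 1)), n)), 1, function(s) {
    Df <- D * s
    mu <- colMeans(Df)
    sdv <- apply(Df, 2, sd)
    tv <- mu / (sdv / sqrt(n))
    assrpac:::.max_cluster_mass(tv, t_crit, nr, nc, adjacency)
  })
}
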