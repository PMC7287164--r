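test_that("asymmetric waveform warps rise/decay while preserving range", {
  th <- seq(0, 4 * pi, length.out = 2001)
  expect_equal(asymmetric_wave(th, 0), cos(th))
  w <- asymmetric_wave(th, 0.4)
  expect_true(all(w >= -1 & w <= 1))
  # rise fraction of the cycle is (1 - a)/2 = 0.3: measure trough -> peak
  one <- asymmetric_wave(seq(0, 2 * pi, length.out = 10001), 0.4)
  i_tr <- which.min(one); i_pk_after <- i_tr + which.max(one[i_tr:10001]) - 1
  rise_frac <- (i_pk_after - i_tr) / 10000
  expect_equal(rise_frac, 0.3, tolerance = 0.01)
})

test_that("1/f noise follows the configured spectral slope", {
  fs <- 200
  for (beta in c(0.5, 1, 1.5)) {
    set.seed(10)
    x <- rowMeans(sapply(1:40, function(i) {
      v <- one_over_f_noise(2048, fs, beta, 1)
      Mod(stats::fft(v))^2
    }))
    f <- (0:2047) * fs / 2048
    sel <- f >= 2 & f <= 80
    fit <- stats::lm(log(x[sel]) ~ log(f[sel]))
    expect_equal(unname(stats::coef(fit)[2]), -beta, tolerance = 0.1)
  }
})

test_that("modulation depth 1 drives the gamma envelope to zero at troughs", {
  spec <- fast_spec()
  tr <- synthesize_trial(spec, coupling_spec(6, 40, 1), quiet_noise(),
                         seed = 2, return_components = TRUE)
  cw <- tr$times_s >= 0 & tr$times_s < 1
  expect_equal(min(tr$gamma_envelope[cw]), 0, tolerance = 1e-3)
  expect_equal(max(tr$gamma_envelope[cw]), 2, tolerance = 1e-3)
  # no modulation outside the coupling window
  expect_true(all(tr$gamma_envelope[!cw] == 1))
})

test_that("m = 0 trials carry band power only at the configured frequencies", {
  spec <- fast_spec()
  tr <- synthesize_trial(spec, coupling_spec(6, 40, 0, gamma_bandwidth_hz = 0),
                         quiet_noise(), seed = 5)
  pw <- Mod(stats::fft(tr$signal))^2
  f <- (seq_along(tr$signal) - 1) * spec$sampling_rate_hz / length(tr$signal)
  half <- f <= spec$sampling_rate_hz / 2
  top <- order(pw[half], decreasing = TRUE)[1:6]
  expect_true(all(abs(f[top] - 6) < 1 | abs(f[top] - 40) < 1))
})

test_that("ensembles are reproducible from their seed and distinct across seeds", {
  spec <- fast_spec()
  a <- synthesize_ensemble(spec, n = 4, seed = 7)
  b <- synthesize_ensemble(spec, n = 4, seed = 7)
  c <- synthesize_ensemble(spec, n = 4, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("sessions carry the oddball plan; cohorts are deterministic", {
  spec <- fast_spec()
  ses <- synthesize_session(spec, seed = 3)
  expect_equal(nrow(ses$data), 100)
  expect_equal(sum(ses$trial_kinds == "standard"), 85)
  coh1 <- generate_cohort(3, spec, n_trials = 5, seed = 11)
  coh2 <- generate_cohort(3, spec, n_trials = 5, seed = 11)
  expect_identical(coh1, coh2)
  # null cohort: no entrained response, no modulation recorded in provenance
  nc <- generate_cohort(2, spec, n_trials = 3, seed = 1, null_cohort = TRUE)
  expect_equal(nc$subj01$ground_truth$coupling$modulation_depth, 0)
  expect_equal(nc$subj01$ground_truth$noise$assr_amplitude, 0)
})

test_that("synthesized coupling is recoverable and grows with depth", {
  # z-PAC at the true cell vs median off-cell z, at increasing m
  spec <- fast_spec()
  pp <- pac_params(fP_grid = c(4, 6, 8, 10, 12), fA_grid = seq(24, 56, 8),
                   n_surrogates = 25, seed = 31)
  margin <- sapply(c(0.2, 0.5, 0.8), function(m) {
    mean(sapply(21:23, function(s) {
      ens <- baseline_subtract(synthesize_ensemble(
        spec, coupling_spec(6, 40, m), noise_spec(), n = 60, seed = s))
      z <- comodulogram(ens, pp, window = "stimulus")$values
      is_true <- outer(rownames(z) == "6", colnames(z) == "40", "&")
      z["6", "40"] - stats::median(z[!is_true])
    }))
  })
  expect_true(all(diff(margin) > 0))
  expect_gt(margin[3], 0)
})

test_that("coupling windows outside the epoch are rejected", {
  spec <- fast_spec()
  expect_error(synthesize_trial(spec, coupling_spec(6, 40, 0.5,
                                                    coupling_window_s = c(0, 2)),
                                quiet_noise(), seed = 1),
               "epoch")
})
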