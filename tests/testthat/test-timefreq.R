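sine_ensemble <- function(f, n_trials = 1, fs = 200, amp = 1, phases = 0) {
  times <- seq(-1.5, 1.5, by = 1 / fs)
  d <- t(sapply(seq_len(n_trials), function(i)
    amp * cos(2 * pi * f * times + phases[((i - 1) %% length(phases)) + 1])))
  trial_ensemble(matrix(d, nrow = n_trials), times, fs)
}

test_that("gaussian width follows sigma = n / (2 pi f)", {
  expect_equal(morlet_sigma(40, 10), 10 / (80 * pi))
  expect_equal(morlet_sigma(4, 10), 10 / (8 * pi))
  f <- c(4, 10, 20, 40, 60)
  expect_true(all(diff(morlet_sigma(f, 10)) < 0))
})

test_that("a unit sinusoid has amplitude ~1, flat and maximal at its frequency", {
  ens <- sine_ensemble(40)
  dec <- morlet_transform(ens, wavelet_params(c(20, 30, 40, 50, 60)))
  amp <- Mod(dec$coeffs[1, , ])
  mid <- abs(ens$times_s) < 1                        # well clear of the edges
  expect_equal(mean(amp[3, mid]), 1, tolerance = 1e-3)
  expect_lt(stats::sd(amp[3, mid]), 1e-3)           # flat
  expect_true(all(apply(amp[, mid], 2, which.max) == 3))
  # linearity
  dec3 <- morlet_transform(sine_ensemble(40, amp = 3),
                           wavelet_params(c(20, 30, 40, 50, 60)))
  expect_equal(Mod(dec3$coeffs[1, 3, mid]), 3 * amp[3, mid], tolerance = 1e-9)
})

test_that("off-peak attenuation matches the gaussian frequency response", {
  ens <- sine_ensemble(40)
  freqs <- c(37, 40, 43, 46)
  dec <- morlet_transform(ens, wavelet_params(freqs))
  mid <- apply(dec$valid_mask, 2, all)
  amp <- rowMeans(Mod(dec$coeffs[1, , mid]))
  for (j in c(1, 3, 4)) {
    sigma_f <- freqs[j] / 10
    predicted <- exp(-(40 - freqs[j])^2 / (2 * sigma_f^2))
    expect_equal(amp[j] / amp[2], predicted, tolerance = 0.02)
  }
})

test_that("impulse response has a gaussian envelope of width sigma(f)", {
  fs <- 200
  times <- seq(-1.5, 1.5, by = 1 / fs)
  d <- matrix(0, 1, length(times)); d[1, 301] <- 1
  ens <- trial_ensemble(d, times, fs)
  dec <- morlet_transform(ens, wavelet_params(20))
  env <- Mod(dec$coeffs[1, 1, ])
  # second-moment width around the impulse
  w <- env / sum(env)
  mu <- sum(times * w)
  sd_t <- sqrt(sum((times - mu)^2 * w))
  expect_equal(mu, times[301], tolerance = 1e-6)
  expect_equal(sd_t, morlet_sigma(20, 10), tolerance = 0.01)
})

test_that("FFT convolution matches naive time-domain convolution", {
  set.seed(9)
  fs <- 100
  times <- seq(0, 2, by = 1 / fs)
  x <- rnorm(length(times))
  ens <- trial_ensemble(matrix(x, 1), times - 1, fs)
  f <- 12
  dec <- morlet_transform(ens, wavelet_params(f))
  k <- assrpac:::.morlet_kernel(f, 10, fs)
  K <- length(k); half <- (K - 1) / 2
  xp <- c(rep(0, K), x, rep(0, K))   # xp[i + K] == x[i], zero outside
  naive <- vapply(seq_along(x), function(n)
    sum(k * xp[n - (seq_len(K) - half - 1) + K]), 0i)
  expect_equal(max(Mod(dec$coeffs[1, 1, ] - naive)) /
                 max(Mod(naive)), 0, tolerance = 1e-10)
})

test_that("frequencies whose sigma exceeds the epoch are rejected by name", {
  ens <- sine_ensemble(40)
  expect_error(morlet_transform(ens, wavelet_params(c(2, 40))), "2 Hz")
})

test_that("baseline-corrected amplitude recovers a mid-epoch step", {
  fs <- 200
  times <- seq(-1.5, 1.5, by = 1 / fs)
  step <- 1 + 1.5 * (times >= 0)           # amplitude 1 -> 2.5 at t = 0
  d <- t(replicate(3, step * cos(2 * pi * 30 * times)))
  ens <- trial_ensemble(d, times, fs)
  amp <- tf_amplitude(morlet_transform(ens, wavelet_params(30)))
  tsel <- times >= 0.4 & times < 0.8
  expect_equal(mean(amp$values[1, tsel]), 1.5, tolerance = 0.02)
  # corrected baseline-window mean is 0 by construction
  bsel <- times >= -1.3 & times < -0.5
  expect_equal(mean(amp$values[1, bsel]), 0, tolerance = 1e-12)
  # stationary signal corrects to ~0 away from the epoch edges
  ens2 <- sine_ensemble(30, n_trials = 2)
  amp2 <- tf_amplitude(morlet_transform(ens2, wavelet_params(30)))
  expect_lt(max(abs(amp2$values[1, abs(ens2$times_s) < 1.2])), 1e-3)
})

test_that("ITC is 1 for identical trials, 0 for balanced phases, Rayleigh for noise", {
  ens <- sine_ensemble(40, n_trials = 5, phases = 0)
  ic <- itc(morlet_transform(ens, wavelet_params(40)))
  mid <- abs(ens$times_s) < 1
  expect_equal(mean(ic$values[1, mid]), 1, tolerance = 1e-9)

  bal <- sine_ensemble(40, n_trials = 4, phases = c(0, pi / 2, pi, 3 * pi / 2))
  icb <- itc(morlet_transform(bal, wavelet_params(40)))
  expect_lt(max(icb$values[1, mid]), 1e-6)

  # common rotation leaves ITC unchanged
  rot <- sine_ensemble(40, n_trials = 4,
                       phases = 1.1 + c(0, pi / 2, pi, 3 * pi / 2))
  icr <- itc(morlet_transform(rot, wavelet_params(40)))
  expect_equal(icr$values, icb$values, tolerance = 1e-9)

  # 85 phase-random trials: E[ITC] ~ sqrt(pi/4)/sqrt(85)
  nz <- noise_ensemble(85, seed = 6)
  icn <- itc(morlet_transform(nz, wavelet_params(40)))
  expect_equal(mean(icn$values[1, abs(nz$times_s) < 1.2]),
               sqrt(pi / 4) / sqrt(85), tolerance = 0.025)

  expect_error(itc(morlet_transform(sine_ensemble(40), wavelet_params(40))),
               "2 trials")
})

test_that("band summaries average the requested band and window", {
  ens <- sine_ensemble(40, n_trials = 2)
  amp <- tf_amplitude(morlet_transform(ens, wavelet_params(c(39, 40, 41))))
  flat <- amp; flat$values[] <- 2.5
  expect_equal(band_summary(flat, c(39, 41), c(0.2, 1.0)), 2.5)
  expect_error(band_summary(amp, c(10, 12), c(0.2, 1.0)), "no cells")
  # 40 Hz summary grows with entrained amplitude
  spec <- fast_spec()
  vals <- sapply(c(0.5, 1, 2), function(a) {
    ens <- baseline_subtract(synthesize_ensemble(
      spec, coupling_spec(6, 40, 0), noise_spec(assr_amplitude = a),
      n = 10, seed = 3))
    am <- tf_amplitude(morlet_transform(ens, wavelet_params(39:41)))
    band_summary(am, c(39, 41), c(0.3, 0.9))
  })
  expect_true(all(diff(vals) > 0))
})
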