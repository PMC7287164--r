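#' Morlet wavelet parameters
#'
#' A family of complex Morlet wavelets `w(t) = exp(2i*pi*f*t) *
#' exp(-t^2 / (2*sigma^2))` with `sigma = n_cycles / (2*pi*f)`, so the number
#' of cycles under the gaussian is constant across frequencies. A fixed
#' `n_cycles = 10` prioritizes frequency resolution (spectral sd
#' `sigma_f = f / n_cycles`).
#'
#' @param freqs_hz Ordered vector of positive analysis frequencies (Hz).
#' @param n_cycles Number of cycles `n` (>= 1), constant over frequencies.
#' @return An object of class `wavelet_params`.
#' @export
wavelet_params <- function(freqs_hz = 1:60, n_cycles = 10) {
  stopifnot(all(freqs_hz > 0), n_cycles >= 1, !is.unsorted(freqs_hz))
  structure(list(freqs_hz = as.numeric(freqs_hz), n_cycles = n_cycles),
            class = "wavelet_params")
}

#' Gaussian width of a Morlet wavelet
#'
#' @param f Frequency in Hz.
#' @param n_cycles Number of cycles.
#' @return `sigma = n_cycles / (2*pi*f)` in seconds.
#' @export
morlet_sigma <- function(f, n_cycles = 10) n_cycles / (2 * pi * f)

# Build one complex Morlet kernel sampled at fs, truncated at +/- 5 sigma
# (gaussian tail < 1e-5). Scaled so that convolution with a unit-amplitude
# sinusoid at f yields coefficient modulus ~ 1.
.morlet_kernel <- function(f, n_cycles, fs) {
  sigma <- morlet_sigma(f, n_cycles)
  half <- ceiling(5 * sigma * fs)
  t <- (-half:half) / fs
  gauss <- exp(-t^2 / (2 * sigma^2))
  k <- exp(2i * pi * f * t) * gauss
  2 * k / sum(gauss)
}

# Precompute FFT'd kernels and geometry for repeated transforms of signals of
# length n_time. Reused heavily by the surrogate loop.
.morlet_plan <- function(n_time, fs, freqs, n_cycles) {
  kernels <- lapply(freqs, .morlet_kernel, n_cycles = n_cycles, fs = fs)
  klen <- vapply(kernels, length, 1L)
  L <- stats::nextn(n_time + max(klen) - 1L, 2)
  kfft <- matrix(0i, L, length(freqs))
  for (j in seq_along(kernels)) {
    kp <- complex(length.out = L)
    kp[seq_len(klen[j])] <- kernels[[j]]
    kfft[, j] <- stats::fft(kp)
  }
  list(L = L, n_time = n_time, fs = fs, freqs = freqs, n_cycles = n_cycles,
       kfft = kfft, center = (klen - 1L) %/% 2L)
}

# Apply the planned transform to X (n_time x n_signals real matrix).
# Returns a list (one element per frequency) of n_time x n_signals complex
# coefficient matrices.
.morlet_apply <- function(plan, X) {
  n <- ncol(X)
  Xp <- matrix(0, plan$L, n)
  Xp[seq_len(plan$n_time), ] <- X
  Xf <- stats::mvfft(Xp)
  lapply(seq_along(plan$freqs), function(j) {
    Y <- stats::mvfft(Xf * plan$kfft[, j], inverse = TRUE) / plan$L
    Y[plan$center[j] + seq_len(plan$n_time), , drop = FALSE]
  })
}

#' Morlet wavelet transform of a trial ensemble
#'
#' Convolves every trial with the complex Morlet kernel at each analysis
#' frequency (FFT-based linear convolution with zero padding). Coefficients
#' are scaled so that a unit-amplitude sinusoid at an analysis frequency has
#' modulus approximately 1 at that frequency. A validity mask flags, per
#' frequency, the samples further than `edge_sigmas * sigma(f)` from both
#' epoch edges; samples outside the mask may be attenuated or distorted by
#' edge effects (zero padding), which matters at low frequencies where
#' `sigma` is large.
#'
#' @param ensemble A [trial_ensemble()].
#' @param params A [wavelet_params()].
#' @param edge_sigmas Multiple of `sigma(f)` defining the edge-contamination
#'   margin of the validity mask.
#' @return An object of class `morlet_decomposition`: `coeffs` (complex array
#'   trials x freqs x time), `freqs_hz`, `times_s`, `params`, `valid_mask`
#'   (freqs x time logical).
#' @export
morlet_transform <- function(ensemble, params, edge_sigmas = 2) {
  stopifnot(inherits(ensemble, "trial_ensemble"), inherits(params, "wavelet_params"))
  times <- ensemble$times_s
  nt <- length(times)
  ntr <- nrow(ensemble$data)
  freqs <- params$freqs_hz

  valid <- matrix(FALSE, length(freqs), nt)
  for (j in seq_along(freqs)) {
    margin <- edge_sigmas * morlet_sigma(freqs[j], params$n_cycles)
    valid[j, ] <- (times - times[1]) > margin & (times[nt] - times) > margin
    if (!any(valid[j, ]))
      stop(sprintf("wavelet at %g Hz: gaussian width (sigma = %.3f s) too large for the epoch",
                   freqs[j], morlet_sigma(freqs[j], params$n_cycles)))
  }

  plan <- .morlet_plan(nt, ensemble$sampling_rate_hz, freqs, params$n_cycles)
  per_freq <- .morlet_apply(plan, t(ensemble$data))
  coeffs <- array(0i, dim = c(ntr, length(freqs), nt))
  for (j in seq_along(freqs)) coeffs[, j, ] <- t(per_freq[[j]])

  structure(list(coeffs = coeffs, freqs_hz = freqs, times_s = times,
                 sampling_rate_hz = ensemble$sampling_rate_hz,
                 params = params, valid_mask = valid),
            class = "morlet_decomposition")
}

#' @export
print.morlet_decomposition <- function(x, ...) {
  cat(sprintf("<morlet_decomposition> %d trials x %d freqs (%g-%g Hz) x %d samples, n_cycles = %g\n",
              dim(x$coeffs)[1], dim(x$coeffs)[2], min(x$freqs_hz), max(x$freqs_hz),
              dim(x$coeffs)[3], x$params$n_cycles))
  invisible(x)
}

#' Baseline-corrected wavelet amplitude
#'
#' Amplitude is the modulus of the wavelet coefficients. The trial-averaged
#' amplitude map is baseline-corrected by subtracting, per frequency, the mean
#' amplitude over the baseline window. Per-trial correction (subtracting each
#' trial's own baseline mean before averaging) is available as an option.
#'
#' @param decomp A [morlet_transform()] result.
#' @param baseline_window Baseline window `(start, end)` seconds, half-open.
#' @param per_trial Logical; correct each trial before averaging.
#' @return An object of class `tf_map`: `values` (freqs x time corrected
#'   trial-average), `uncorrected` (freqs x time), `freqs_hz`, `times_s`, and
#'   if `per_trial`, `trial_values` (trials x freqs x time).
#' @export
tf_amplitude <- function(decomp, baseline_window = c(-1.3, -0.5),
                         per_trial = FALSE) {
  stopifnot(inherits(decomp, "morlet_decomposition"))
  idx <- window_index(decomp$times_s, baseline_window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  amp <- Mod(decomp$coeffs)                       # trials x freqs x time
  avg <- apply(amp, c(2, 3), mean)                # freqs x time
  trial_values <- NULL
  if (per_trial) {
    base_tr <- apply(amp[, , idx, drop = FALSE], c(1, 2), mean)
    trial_values <- sweep(amp, c(1, 2), base_tr)
    corrected <- apply(trial_values, c(2, 3), mean)
  } else {
    corrected <- avg - rowMeans(avg[, idx, drop = FALSE])
  }
  structure(list(values = corrected, uncorrected = avg,
                 trial_values = trial_values,
                 freqs_hz = decomp$freqs_hz, times_s = decomp$times_s,
                 baseline_window = baseline_window),
            class = "tf_map")
}

#' Inter-trial phase coherence
#'
#' `ITC(f, t)` is the modulus of the across-trials mean of the unit phase
#' vectors `exp(i * phase)`. 1 means perfect phase locking across trials, and
#' values near `sqrt(pi/4)/sqrt(n)` are expected for random phases.
#'
#' @param decomp A [morlet_transform()] result with at least 2 trials.
#' @return A `tf_map` whose `values` are the freqs x time ITC in `[0, 1]`.
#' @export
itc <- function(decomp) {
  stopifnot(inherits(decomp, "morlet_decomposition"))
  if (dim(decomp$coeffs)[1] < 2)
    stop("ITC requires at least 2 trials")
  m <- Mod(decomp$coeffs)
  unit <- decomp$coeffs / ifelse(m > 0, m, 1)
  vals <- Mod(apply(unit, c(2, 3), mean))
  structure(list(values = vals, freqs_hz = decomp$freqs_hz,
                 times_s = decomp$times_s),
            class = "tf_map")
}

#' Scalar band/window summary of a time-frequency map
#'
#' Mean of the map over an inclusive frequency band and a half-open time
#' window; used e.g. for per-subject 40-Hz ASSR amplitude summaries.
#'
#' @param tfmap A `tf_map` (from [tf_amplitude()] or [itc()]).
#' @param band_hz Two-element inclusive frequency band.
#' @param window_s Two-element half-open time window in seconds.
#' @return A scalar.
#' @export
band_summary <- function(tfmap, band_hz, window_s) {
  stopifnot(inherits(tfmap, "tf_map"), length(band_hz) == 2)
  fsel <- which(tfmap$freqs_hz >= band_hz[1] & tfmap$freqs_hz <= band_hz[2])
  tsel <- window_index(tfmap$times_s, window_s)
  if (length(fsel) == 0 || length(tsel) == 0)
    stop("band/window selects no cells")
  mean(tfmap$values[fsel, tsel, drop = FALSE])
}
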