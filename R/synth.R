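#' Cross-frequency coupling specification for synthetic trials
#'
#' Parameters of the modulated-carrier model used by the generator: a
#' low-frequency oscillation at `phase_freq_hz` whose instantaneous waveform
#' value modulates the amplitude envelope of a gamma carrier at `amp_freq_hz`,
#' with depth `modulation_depth`, inside `coupling_window_s`.
#'
#' @param phase_freq_hz Modulating (phase-providing) frequency fP, 4-12 Hz.
#' @param amp_freq_hz Modulated (amplitude-providing) frequency fA, 13-60 Hz.
#' @param modulation_depth m in `[0, 1]`; 0 = no coupling, 1 = envelope
#'   reaches zero at the low-frequency trough.
#' @param phase_amp_ratio Amplitude of the low-frequency oscillation relative
#'   to the gamma carrier (unit carrier amplitude). Default 3, reflecting the
#'   1/f dominance of slow rhythms in cortical recordings.
#' @param coupling_window_s Interval of the epoch in which the modulation is
#'   active; outside it the gamma envelope is constant.
#' @param waveform_asymmetry Rise/decay skew of the low-frequency waveform in
#'   (-1, 1): 0 gives a sinusoid; positive values compress the trough-to-peak
#'   rise to a fraction `(1 - asymmetry)/2` of the cycle.
#' @param gamma_bandwidth_hz Spectral linewidth (Hz) of the gamma carrier,
#'   implemented as phase diffusion. Endogenous gamma is not a coherent tone:
#'   a finite linewidth (default 2 Hz, coherence time ~0.5 s) keeps the
#'   carrier from locking into a fixed phase relation with the entrained
#'   steady-state response over a whole trial. 0 gives a pure tone.
#' @param modulate_entrained Logical; if TRUE (default) the low-frequency
#'   phase modulates the gain of the total gamma-band activity, entrained
#'   response included, as expected if slow oscillations modulate cortical
#'   gamma gain as a whole. If FALSE only the endogenous gamma carrier is
#'   modulated and the entrained response rides on top unmodulated, in which
#'   case interference between the two same-frequency components dilutes the
#'   measurable coupling.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(phase_freq_hz = 6,
                          amp_freq_hz = 40,
                          modulation_depth = 0.8,
                          phase_amp_ratio = 3,
                          coupling_window_s = c(0, 1),
                          waveform_asymmetry = 0,
                          gamma_bandwidth_hz = 2,
                          modulate_entrained = TRUE) {
  stopifnot(phase_freq_hz >= 4, phase_freq_hz <= 12,
            amp_freq_hz >= 13, amp_freq_hz <= 60,
            modulation_depth >= 0, modulation_depth <= 1,
            phase_amp_ratio >= 0,
            length(coupling_window_s) == 2,
            coupling_window_s[1] < coupling_window_s[2],
            abs(waveform_asymmetry) < 1, gamma_bandwidth_hz >= 0)
  structure(list(phase_freq_hz = phase_freq_hz,
                 amp_freq_hz = amp_freq_hz,
                 modulation_depth = modulation_depth,
                 phase_amp_ratio = phase_amp_ratio,
                 coupling_window_s = as.numeric(coupling_window_s),
                 waveform_asymmetry = waveform_asymmetry,
                 gamma_bandwidth_hz = gamma_bandwidth_hz,
                 modulate_entrained = modulate_entrained),
            class = "coupling_spec")
}

#' Background-activity specification for synthetic trials
#'
#' @param one_over_f_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_sd Standard deviation of the additive 1/f noise (same
#'   arbitrary source units as the oscillatory components).
#' @param assr_amplitude Amplitude of the entrained steady-state sinusoid at
#'   the stimulation frequency.
#' @param assr_onset_s,assr_offset_s Interval over which the entrained
#'   response is active (defaults: the 1-s click train).
#' @param assr_ramp_s Raised-cosine rise/fall time of the entrained response.
#'   Entrainment builds up and releases over ~100-200 ms rather than stepping
#'   on instantaneously; a hard step would add a phase-locked broadband
#'   transient that contaminates the phase estimates at all low frequencies.
#' @param itc_jitter_rad SD (radians) of per-trial phase jitter of the
#'   entrained response; 0 gives a fully phase-locked response (ITC ~ 1),
#'   large values degrade ITC towards 0.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1,
                       noise_sd = 1,
                       assr_amplitude = 1,
                       assr_onset_s = 0,
                       assr_offset_s = 1,
                       assr_ramp_s = 0.15,
                       itc_jitter_rad = 0) {
  stopifnot(noise_sd >= 0, assr_amplitude >= 0,
            assr_onset_s < assr_offset_s, assr_ramp_s >= 0,
            2 * assr_ramp_s <= assr_offset_s - assr_onset_s,
            itc_jitter_rad >= 0)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 noise_sd = noise_sd,
                 assr_amplitude = assr_amplitude,
                 assr_onset_s = assr_onset_s,
                 assr_offset_s = assr_offset_s,
                 assr_ramp_s = assr_ramp_s,
                 itc_jitter_rad = itc_jitter_rad),
            class = "noise_spec")
}

#' Asymmetric low-frequency waveform
#'
#' Periodic waveform in `[-1, 1]` built by asymmetric time-warping of one
#' cosine cycle: the trough-to-peak rise occupies a fraction
#' `(1 - asymmetry)/2` of the cycle and the peak-to-trough decay the
#' complement, preserving the fundamental frequency. `asymmetry = 0` returns
#' `cos(phase)` exactly; the rise/decay duration ratio is
#' `(1 - asymmetry) / (1 + asymmetry)`.
#'
#' @param phase Instantaneous phase in radians (peak at phase 0 mod 2pi).
#' @param asymmetry Skew parameter in (-1, 1).
#' @return Numeric vector of waveform values.
#' @export
asymmetric_wave <- function(phase, asymmetry = 0) {
  stopifnot(abs(asymmetry) < 1)
  if (asymmetry == 0) return(cos(phase))
  r <- (1 - asymmetry) / 2   # rise (trough -> peak) fraction of the cycle
  d <- 1 - r                 # decay (peak -> trough) fraction
  v <- (phase / (2 * pi)) %% 1
  psi <- ifelse(v < d, pi * v / d, pi + pi * (v - d) / r)
  cos(psi)
}

#' Generate 1/f^beta noise by spectral shaping
#'
#' White gaussian noise is shaped in the frequency domain with an
#' `|f|^(-beta/2)` amplitude mask (zero DC), giving a stationary background
#' with power spectral density proportional to `f^(-beta)`, then rescaled to
#' the requested standard deviation.
#'
#' @param n Number of samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param exponent Spectral slope beta (power ~ f^-beta).
#' @param sd Target standard deviation of the output.
#' @return Numeric vector of length `n`. Uses the current RNG stream.
#' @export
one_over_f_noise <- function(n, sampling_rate_hz, exponent = 1, sd = 1) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1)) * sampling_rate_hz / n
  f <- pmin(f, sampling_rate_hz - f)  # fold to |f| for the two-sided spectrum
  mask <- c(0, abs(f[-1])^(-exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

# One epoch of the modulated-carrier model. Assumes the RNG is already seeded
# by the caller; draw order (low phase, gamma phase, ASSR jitter, noise) is
# part of the reproducibility contract.
.synth_trial <- function(spec, coupling, noise, return_components = FALSE) {
  fs <- spec$sampling_rate_hz
  times <- seq(spec$epoch_window_s[1], spec$epoch_window_s[2], by = 1 / fs)
  cw <- coupling$coupling_window_s
  if (cw[1] < spec$epoch_window_s[1] || cw[2] > spec$epoch_window_s[2])
    stop("coupling_window_s must lie within the epoch window")

  theta0 <- stats::runif(1, 0, 2 * pi)
  w_low <- asymmetric_wave(2 * pi * coupling$phase_freq_hz * times + theta0,
                           coupling$waveform_asymmetry)
  x_low <- coupling$phase_amp_ratio * w_low

  gamma0 <- stats::runif(1, 0, 2 * pi)
  in_cw <- as.numeric(times >= cw[1] & times < cw[2])
  env <- 1 + coupling$modulation_depth * w_low * in_cw
  gphase <- 2 * pi * coupling$amp_freq_hz * times + gamma0
  if (coupling$gamma_bandwidth_hz > 0) {
    # phase diffusion giving a Lorentzian line of FWHM ~ gamma_bandwidth_hz
    dphi <- stats::rnorm(length(times), 0,
                         sqrt(2 * pi * coupling$gamma_bandwidth_hz / fs))
    gphase <- gphase + cumsum(dphi)
  }
  carrier <- cos(gphase)

  assr_phase <- if (noise$itc_jitter_rad > 0)
    stats::rnorm(1, 0, noise$itc_jitter_rad) else 0
  in_assr <- as.numeric(times >= noise$assr_onset_s & times < noise$assr_offset_s)
  if (noise$assr_ramp_s > 0) {
    up <- (times - noise$assr_onset_s) / noise$assr_ramp_s
    down <- (noise$assr_offset_s - times) / noise$assr_ramp_s
    in_assr <- in_assr * 0.5 * (1 - cospi(pmin(pmax(up, 0), 1))) *
      0.5 * (1 - cospi(pmin(pmax(down, 0), 1)))
  }
  x_assr <- noise$assr_amplitude *
    sin(2 * pi * spec$stim_freq_hz * times + assr_phase) * in_assr

  if (isTRUE(coupling$modulate_entrained)) {
    x_assr <- env * x_assr
    x_gamma <- env * carrier
  } else {
    x_gamma <- env * carrier
  }

  x_noise <- one_over_f_noise(length(times), fs, noise$one_over_f_exponent,
                              noise$noise_sd)
  x <- x_low + x_gamma + x_assr + x_noise
  if (return_components)
    list(signal = x, times_s = times, low = x_low, gamma = x_gamma,
         gamma_envelope = env, assr = x_assr, noise = x_noise)
  else
    list(signal = x, times_s = times)
}

#' Synthesize a single epoch
#'
#' One trial of the generative model: low-frequency oscillation with random
#' phase (optionally skewed), a gamma carrier whose envelope is
#' `1 + m * w_low(t)` inside the coupling window, a phase-locked (or jittered)
#' entrained sinusoid at the stimulation frequency, and additive 1/f noise.
#'
#' @param spec A [paradigm_spec()].
#' @param coupling A [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed (reproducible), or NULL to use the current RNG.
#' @param return_components Also return the individual signal components.
#' @return A list with `signal`, `times_s`, and components if requested.
#' @export
synthesize_trial <- function(spec, coupling = coupling_spec(),
                             noise = noise_spec(), seed = NULL,
                             return_components = FALSE) {
  stopifnot(inherits(spec, "paradigm_spec"), inherits(coupling, "coupling_spec"),
            inherits(noise, "noise_spec"))
  with_local_seed(seed, .synth_trial(spec, coupling, noise, return_components))
}

#' Synthesize an ensemble of analysis trials
#'
#' Generates `n` independent trials under one coupling/noise configuration,
#' all tagged "standard". For a full session with oddball placement see
#' [synthesize_session()].
#'
#' @param spec A [paradigm_spec()].
#' @param coupling A [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param n Number of trials (default: the spec's standard-trial count).
#' @param seed Integer seed; the whole ensemble is reproducible from it.
#' @param condition_label Label stored on the ensemble.
#' @return A [trial_ensemble()] with ground-truth provenance attached.
#' @export
synthesize_ensemble <- function(spec, coupling = coupling_spec(),
                                noise = noise_spec(),
                                n = spec$n_trials_total - spec$n_oddball,
                                seed = 1L,
                                condition_label = paste0(spec$stim_freq_hz, "Hz")) {
  stopifnot(n >= 1)
  out <- with_local_seed(seed, {
    first <- .synth_trial(spec, coupling, noise)
    data <- matrix(0, nrow = n, ncol = length(first$signal))
    data[1, ] <- first$signal
    if (n > 1) for (i in 2:n) data[i, ] <- .synth_trial(spec, coupling, noise)$signal
    list(data = data, times = first$times_s)
  })
  trial_ensemble(out$data, out$times, spec$sampling_rate_hz, condition_label,
                 trial_kinds = rep("standard", n),
                 ground_truth = list(coupling = coupling, noise = noise,
                                     seed = seed))
}

#' Synthesize a full oddball session
#'
#' Generates all `n_trials_total` trials with oddball placement from
#' [generate_session_plan()]. At source level, oddball trials follow the same
#' generative law (the deviance is in the tone carrier, not the entrainment);
#' they differ only in their `trial_kinds` tag, which
#' [select_analysis_trials()] uses to exclude them.
#'
#' @inheritParams synthesize_ensemble
#' @return A [trial_ensemble()] with `trial_kinds` set from the session plan.
#' @export
synthesize_session <- function(spec, coupling = coupling_spec(),
                               noise = noise_spec(), seed = 1L,
                               condition_label = paste0(spec$stim_freq_hz, "Hz")) {
  seeds <- derive_seeds(seed, 2)
  plan <- generate_session_plan(spec, seeds[1])
  ens <- synthesize_ensemble(spec, coupling, noise, n = spec$n_trials_total,
                             seed = seeds[2], condition_label = condition_label)
  ens$trial_kinds <- plan$kind
  ens$ground_truth$session_plan <- plan
  ens$ground_truth$seed <- seed
  ens
}

#' Generate a cohort of synthetic subjects
#'
#' One trial ensemble per subject, each with its own derived seed. Stimulus
#' and baseline analysis windows are taken from the same epochs downstream.
#' In `null_cohort` mode the stimulation window carries no coupling and no
#' entrained response beyond the stationary background, so stimulus and
#' baseline comodulograms are draws from the identical generative process —
#' the exchangeable null for calibrating the cluster permutation test.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param spec A [paradigm_spec()].
#' @param coupling A [coupling_spec()]; ignored in `null_cohort` mode except
#'   for its frequencies and window.
#' @param noise A [noise_spec()].
#' @param n_trials Trials per subject (default: the spec's standard count).
#' @param seed Master seed; the cohort is deterministic from it.
#' @param null_cohort Logical; force zero modulation depth and zero entrained
#'   amplitude so the whole epoch is stationary.
#' @return A list of [trial_ensemble()] objects named `subj01`, `subj02`, ...
#' @export
generate_cohort <- function(n_subjects, spec, coupling = coupling_spec(),
                            noise = noise_spec(),
                            n_trials = spec$n_trials_total - spec$n_oddball,
                            seed = 1L, null_cohort = FALSE) {
  stopifnot(n_subjects >= 2)
  if (null_cohort) {
    coupling$modulation_depth <- 0
    noise$assr_amplitude <- 0
  }
  seeds <- derive_seeds(seed, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i)
    synthesize_ensemble(spec, coupling, noise, n = n_trials, seed = seeds[i]))
  names(subjects) <- sprintf("subj%02d", seq_len(n_subjects))
  subjects
}
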