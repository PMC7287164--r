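#' Paradigm specification for an ASSR click-train session
#'
#' Describes the auditory steady-state response (ASSR) oddball paradigm: a
#' click train of brief tones repeated at the stimulation frequency, presented
#' over blocked trials with a minority of oddball (deviant-carrier) trials.
#' The spec drives both the synthetic session generator and the epoch geometry
#' used by the analysis windows.
#'
#' @param stim_freq_hz Click repetition rate in Hz; the entrainment frequency.
#'   Typical conditions are 40, 30 and 20 Hz.
#' @param train_duration_s Duration of the click train in seconds. The product
#'   `stim_freq_hz * train_duration_s` must be a whole number of clicks.
#' @param tone_duration_ms Duration of each click tone in milliseconds.
#' @param n_trials_total Total trials per session (standards + oddballs).
#' @param n_oddball Number of oddball trials, placed uniformly at random
#'   across the session; oddballs are excluded from analysis.
#' @param n_blocks Number of blocks; `n_trials_total` must divide evenly.
#' @param sampling_rate_hz Sampling rate of the recorded/synthesized data.
#' @param epoch_window_s Two-element numeric, epoch limits in seconds relative
#'   to stimulus onset.
#'
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(stim_freq_hz = 40,
                          train_duration_s = 1.0,
                          tone_duration_ms = 1,
                          n_trials_total = 100,
                          n_oddball = 15,
                          n_blocks = 10,
                          sampling_rate_hz = 1000,
                          epoch_window_s = c(-1.5, 1.5)) {
  stopifnot(stim_freq_hz > 0, train_duration_s > 0, tone_duration_ms > 0,
            sampling_rate_hz > 0, length(epoch_window_s) == 2)
  n_clicks <- stim_freq_hz * train_duration_s
  if (abs(n_clicks - round(n_clicks)) > 1e-9)
    stop("stim_freq_hz * train_duration_s must be a whole number of clicks (got ",
         n_clicks, ")")
  if (n_oddball >= n_trials_total)
    stop("n_oddball must be smaller than n_trials_total")
  if (n_trials_total %% n_blocks != 0)
    stop("n_trials_total must be divisible by n_blocks")
  if (epoch_window_s[1] >= epoch_window_s[2])
    stop("epoch_window_s must be an increasing interval")
  structure(list(stim_freq_hz = stim_freq_hz,
                 train_duration_s = train_duration_s,
                 tone_duration_ms = tone_duration_ms,
                 n_trials_total = as.integer(n_trials_total),
                 n_oddball = as.integer(n_oddball),
                 n_blocks = as.integer(n_blocks),
                 sampling_rate_hz = sampling_rate_hz,
                 epoch_window_s = as.numeric(epoch_window_s)),
            class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf("<paradigm_spec> %g Hz click train, %g s, %d trials (%d oddball) in %d blocks, fs = %g Hz\n",
              x$stim_freq_hz, x$train_duration_s, x$n_trials_total,
              x$n_oddball, x$n_blocks, x$sampling_rate_hz))
  invisible(x)
}

#' Generate the click train for one trial
#'
#' Produces the click onset times and a sample-level 0/1 pulse sequence for
#' one presentation of the train. Clicks are spaced `1/stim_freq_hz` apart
#' starting at time 0 and each pulse lasts `tone_duration_ms`. The oddball
#' flag only changes the tone carrier (2000 Hz instead of 1000 Hz); timing is
#' identical for standard and oddball trains.
#'
#' @param spec A [paradigm_spec()].
#' @param oddball Logical; tag the train as an oddball (deviant carrier).
#' @return A list with `onsets_s` (click onset times), `pulse` (0/1 vector
#'   sampled at `sampling_rate_hz` over `[0, train_duration_s)`), `times_s`
#'   (sample times of `pulse`), and `carrier_hz`.
#' @export
generate_click_train <- function(spec, oddball = FALSE) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n_clicks <- round(spec$stim_freq_hz * spec$train_duration_s)
  onsets <- (seq_len(n_clicks) - 1) / spec$stim_freq_hz
  fs <- spec$sampling_rate_hz
  n_samp <- round(spec$train_duration_s * fs)
  times <- (seq_len(n_samp) - 1) / fs
  pulse_len <- max(1L, round(spec$tone_duration_ms / 1000 * fs))
  pulse <- integer(n_samp)
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    idx <- i0:min(i0 + pulse_len - 1L, n_samp)
    pulse[idx] <- 1L
  }
  list(onsets_s = onsets, pulse = pulse, times_s = times,
       carrier_hz = if (oddball) 2000 else 1000)
}

#' Generate a randomized session plan
#'
#' Lays out the ordered trial list for one session: `n_trials_total` trials in
#' `n_blocks` blocks, with exactly `n_oddball` oddball trials assigned
#' uniformly at random across the whole session (not block-balanced, matching
#' the oddball-count report task). Oddball trials are excluded from analysis
#' by [select_analysis_trials()].
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed controlling oddball placement.
#' @return A data.frame with columns `trial_index`, `block`, `kind`
#'   ("standard"/"oddball").
#' @export
generate_session_plan <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n <- spec$n_trials_total
  per_block <- n %/% spec$n_blocks
  kind <- rep("standard", n)
  if (spec$n_oddball > 0) {
    odd_slots <- with_local_seed(seed, sample.int(n, spec$n_oddball))
    kind[odd_slots] <- "oddball"
  }
  data.frame(trial_index = seq_len(n),
             block = rep(seq_len(spec$n_blocks), each = per_block),
             kind = kind,
             stringsAsFactors = FALSE)
}
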