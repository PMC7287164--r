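# Locate alternating troughs and peaks of a (near-)oscillatory signal.
# Candidate extrema are slope sign changes; runs of same-type extrema are
# collapsed to the most extreme one so the returned sequence alternates.
.alternating_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  nz <- which(s != 0)
  if (length(nz) < 2) return(NULL)
  idx <- integer(0); type <- integer(0)   # +1 peak, -1 trough
  prev <- s[nz[1]]
  for (k in nz[-1]) {
    if (s[k] != prev) {
      idx <- c(idx, k)                    # extremum between sample k and k+1
      type <- c(type, prev)
      prev <- s[k]
    }
  }
  if (length(idx) == 0) return(NULL)
  keep_i <- idx[1]; keep_t <- type[1]
  out_i <- integer(0); out_t <- integer(0)
  for (k in seq_along(idx)[-1]) {
    if (type[k] == keep_t) {
      better <- if (keep_t == 1L) x[idx[k]] > x[keep_i] else x[idx[k]] < x[keep_i]
      if (better) keep_i <- idx[k]
    } else {
      out_i <- c(out_i, keep_i); out_t <- c(out_t, keep_t)
      keep_i <- idx[k]; keep_t <- type[k]
    }
  }
  out_i <- c(out_i, keep_i); out_t <- c(out_t, keep_t)
  list(index = out_i, type = out_t)
}

#' Rise-decay ratio of the low-frequency waveform
#'
#' Measures waveform asymmetry as the ratio of the mean trough-to-peak (rise)
#' duration to the mean peak-to-trough (decay) duration; 1 for a symmetric
#' (sinusoidal) waveform. Departures from 1 in the phase-providing signal can
#' generate spurious phase-amplitude coupling, so the ratio is compared
#' between the stimulation and baseline windows as a control. Extrema are
#' located on a harmonic-preserving narrowband reconstruction: the sum of the
#' real parts of Morlet transforms at `fP, 2*fP, ..., n_harmonics*fP` (a
#' single 10-cycle band at fP alone would remove the harmonics that carry the
#' asymmetry and force the ratio to 1).
#'
#' @param ensemble A [trial_ensemble()].
#' @param fP_hz Fundamental frequency of the low-frequency waveform (Hz).
#' @param window Half-open `(start, end)` analysis window in seconds; must
#'   contain at least 2 full cycles at `fP_hz`.
#' @param n_harmonics Number of harmonics (including the fundamental) kept in
#'   the reconstruction; harmonics above Nyquist are dropped.
#' @param n_cycles Wavelet cycles used for the reconstruction bands.
#' @return An object of class `rise_decay_result`: `ratios` (per trial),
#'   `ratio` (trial mean), `n_cycles_used` (per-trial count of rise/decay
#'   pairs), `fP_hz`, `window`.
#' @export
rise_decay_ratio <- function(ensemble, fP_hz, window, n_harmonics = 3,
                             n_cycles = 10) {
  stopifnot(inherits(ensemble, "trial_ensemble"), fP_hz > 0)
  if (diff(window) * fP_hz < 2)
    stop("window must contain at least 2 full cycles at fP_hz")
  fs <- ensemble$sampling_rate_hz
  harm <- fP_hz * seq_len(n_harmonics)
  harm <- harm[harm < fs / 2]
  dec <- morlet_transform(ensemble, wavelet_params(harm, n_cycles))
  recon <- apply(Re(dec$coeffs), c(1, 3), sum)      # trials x time
  idx <- window_index(ensemble$times_s, window)
  tw <- ensemble$times_s[idx]

  ratios <- apply(recon[, idx, drop = FALSE], 1, function(x) {
    ex <- .alternating_extrema(x)
    if (is.null(ex) || length(ex$index) < 3)
      stop("fewer than 2 trough/peak alternations found in the window")
    tt <- tw[ex$index]
    durs <- diff(tt)
    rise <- durs[ex$type[-length(ex$type)] == -1L]   # trough -> peak
    decay <- durs[ex$type[-length(ex$type)] == 1L]   # peak -> trough
    if (length(rise) == 0 || length(decay) == 0)
      stop("fewer than 2 trough/peak alternations found in the window")
    mean(rise) / mean(decay)
  })
  structure(list(ratios = ratios, ratio = mean(ratios),
                 n_cycles_used = floor(diff(window) * fP_hz),
                 fP_hz = fP_hz, window = window),
            class = "rise_decay_result")
}

#' @export
print.rise_decay_result <- function(x, ...) {
  cat(sprintf("<rise_decay_result> fP = %g Hz, window [%g, %g) s: mean ratio %.3f over %d trials\n",
              x$fP_hz, x$window[1], x$window[2], x$ratio, length(x$ratios)))
  invisible(x)
}

#' Compare rise-decay ratios between stimulation and baseline
#'
#' Paired t-test on per-subject mean ratios with Bonferroni correction for
#' the number of comparisons (e.g. one per low frequency tested).
#'
#' @param stim_ratios,base_ratios Numeric vectors of per-subject mean ratios,
#'   paired by position.
#' @param n_comparisons Bonferroni multiplier; corrected p is capped at 1.
#' @return A list with `t`, `df`, `p_uncorrected`, `p_corrected`,
#'   `mean_difference`.
#' @export
compare_rise_decay <- function(stim_ratios, base_ratios, n_comparisons = 1) {
  stopifnot(length(stim_ratios) == length(base_ratios), n_comparisons >= 1)
  n <- length(stim_ratios)
  if (n < 3) stop("paired comparison requires at least 3 subjects")
  d <- stim_ratios - base_ratios
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      tval <- 0; p <- 1
    } else stop("zero-variance nonzero difference; paired t undefined")
  } else {
    tval <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), df = n - 1)
  }
  list(t = tval, df = n - 1, p_uncorrected = p,
       p_corrected = min(1, p * n_comparisons),
       mean_difference = mean(d))
}
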