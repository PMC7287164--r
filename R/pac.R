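#' Parameters for across-trials mean-vector-length PAC
#'
#' Defines the comodulogram grid (phase frequencies fP, amplitude frequencies
#' fA), wavelet width, surrogate count, and the analysis windows. The default
#' grids span theta/alpha phase (4-12 Hz) against beta/gamma amplitude
#' (13-60 Hz) at 1-Hz steps with 10-cycle wavelets.
#'
#' @param fP_grid Phase-providing frequencies (Hz) within `[4, 12]`.
#' @param fA_grid Amplitude-providing frequencies (Hz) within `[13, 60]`.
#' @param n_cycles Wavelet cycles for both grids.
#' @param n_surrogates Number of segment-swap surrogates used for z-scoring.
#' @param stim_window_s Steady-state window, half-open seconds.
#' @param baseline_window_s Baseline window, half-open seconds.
#' @param normalization_window_s Window over which the per-trial min-max
#'   amplitude normalization is computed.
#' @param surrogate_segments Number of segments the raw signal is cut into
#'   (and randomly reordered) per surrogate; 2 is a single cut-and-swap.
#' @param surrogate_mode "per_trial" (default) draws independent cuts per
#'   trial, giving every trial its own random phase offset; this is required
#'   for an across-trials statistic, because a cut common to all trials only
#'   rotates every trial's low-frequency phase by the same angle, and the
#'   mean vector length is invariant to a common rotation (such surrogates
#'   would preserve the very coupling they are meant to destroy). "common"
#'   applies one cut set to all trials and is retained for comparison
#'   studies.
#' @param seed Integer seed for the surrogate randomization.
#' @return An object of class `pac_params`.
#' @export
pac_params <- function(fP_grid = 4:12, fA_grid = 13:60, n_cycles = 10,
                       n_surrogates = 250,
                       stim_window_s = c(0.2, 1.0),
                       baseline_window_s = c(-1.3, -0.5),
                       normalization_window_s = c(-1.3, 1.3),
                       surrogate_segments = 2,
                       surrogate_mode = c("per_trial", "common"),
                       seed = 1L) {
  stopifnot(all(fP_grid >= 4 & fP_grid <= 12),
            all(fA_grid >= 13 & fA_grid <= 60),
            n_cycles >= 1, n_surrogates >= 1, surrogate_segments >= 2,
            stim_window_s[1] < stim_window_s[2],
            baseline_window_s[1] < baseline_window_s[2],
            normalization_window_s[1] < normalization_window_s[2])
  structure(list(fP_grid = as.numeric(fP_grid), fA_grid = as.numeric(fA_grid),
                 n_cycles = n_cycles, n_surrogates = as.integer(n_surrogates),
                 stim_window_s = stim_window_s,
                 baseline_window_s = baseline_window_s,
                 normalization_window_s = normalization_window_s,
                 surrogate_segments = as.integer(surrogate_segments),
                 surrogate_mode = match.arg(surrogate_mode),
                 seed = seed),
            class = "pac_params")
}

#' Min-max amplitude normalization
#'
#' Rescales each row (trial) of an amplitude series to `[0, 1]` using the
#' minimum and maximum over the normalization window, reducing the bias that
#' large trial-wise amplitude variations would otherwise impose on the
#' across-trials mean vector. A constant (degenerate) row maps to all zeros
#' with a warning.
#'
#' @param x Numeric matrix, trials x time.
#' @param times_s Optional time axis; with `window`, restricts where min/max
#'   are taken. Values outside the window are transformed with the same
#'   affine map, so they may fall outside `[0, 1]`.
#' @param window Optional `(start, end)` half-open normalization window.
#' @return Matrix of the same shape.
#' @export
minmax_normalize <- function(x, times_s = NULL, window = NULL) {
  x <- as.matrix(x)
  stopifnot(all(is.finite(x)))
  idx <- if (!is.null(window)) {
    stopifnot(!is.null(times_s))
    window_index(times_s, window)
  } else seq_len(ncol(x))
  if (length(idx) == 0) stop("normalization window contains no samples")
  lo <- apply(x[, idx, drop = FALSE], 1, min)
  hi <- apply(x[, idx, drop = FALSE], 1, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning(sum(flat), " constant trial(s) normalized to all zeros")
    rng[flat] <- 1
  }
  out <- (x - lo) / rng
  out[flat, ] <- 0
  out
}

#' Across-trials mean vector length
#'
#' At each time sample, the amplitude-weighted unit phase vectors of all
#' trials are averaged and the modulus taken:
#' `MVL(tau) = | (1/n) * sum_t a[t, tau] * exp(i * phi[t, tau]) |`;
#' the returned statistic is the mean of `MVL(tau)` over the window samples.
#' Amplitudes that are independent of phase give small MVL; amplitudes
#' concentrated at a preferred phase give large MVL.
#'
#' @param phase Trials x time matrix of phase angles (radians).
#' @param amp Trials x time matrix of (normalized) amplitudes, same shape.
#' @param times_s Optional time axis for window selection.
#' @param window Optional `(start, end)` half-open window; default all samples.
#' @return Scalar raw MVL.
#' @export
mvl_pac <- function(phase, amp, times_s = NULL, window = NULL) {
  phase <- as.matrix(phase); amp <- as.matrix(amp)
  if (!all(dim(phase) == dim(amp)))
    stop("phase and amp must have identical trials x time dimensions")
  n <- nrow(phase)
  if (n < 2) stop("MVL requires at least 2 trials")
  idx <- if (!is.null(window)) {
    stopifnot(!is.null(times_s))
    window_index(times_s, window)
  } else seq_len(ncol(phase))
  x <- colSums(amp[, idx, drop = FALSE] * cos(phase[, idx, drop = FALSE]))
  y <- colSums(amp[, idx, drop = FALSE] * sin(phase[, idx, drop = FALSE]))
  mean(sqrt(x^2 + y^2)) / n
}

#' Segment-swap surrogate of a time series
#'
#' Cuts the series at `k - 1` points and randomly reorders the segments
#' (for `k = 2`, swaps the two halves at one cut). This destroys the
#' alignment between low-frequency phase and high-frequency amplitude while
#' preserving the waveform shape, amplitude distribution and (up to boundary
#' effects) the power spectrum.
#'
#' @param x Numeric vector.
#' @param cuts Integer cut position(s) in `1..(length(x) - 1)`: segment `i`
#'   ends at `cuts[i]`.
#' @return Permuted numeric vector of the same length. Segment order is drawn
#'   from the current RNG stream (for a single cut the swap is deterministic).
#' @export
segment_swap <- function(x, cuts) {
  n <- length(x)
  cuts <- sort(unique(as.integer(cuts)))
  stopifnot(all(cuts >= 1), all(cuts < n))
  bounds <- c(0L, cuts, n)
  segs <- lapply(seq_len(length(bounds) - 1L),
                 function(i) x[(bounds[i] + 1L):bounds[i + 1L]])
  ord <- if (length(segs) == 2L) c(2L, 1L) else sample(length(segs))
  unlist(segs[ord], use.names = FALSE)
}

#' z-score an observed PAC value against its surrogate distribution
#'
#' @param observed Observed raw MVL.
#' @param surrogates Vector of surrogate MVL values.
#' @return `(observed - mean(surrogates)) / sd(surrogates)` with sample sd
#'   (denominator `n - 1`).
#' @export
z_score_pac <- function(observed, surrogates) {
  s <- stats::sd(surrogates)
  if (!is.finite(s) || s == 0) stop("degenerate surrogate distribution (sd = 0)")
  (observed - mean(surrogates)) / s
}

# --- internal engine -------------------------------------------------------

# MVL over an fA grid for one phase frequency and one window.
# cw, sw: trials x Tw matrices of cos(phase), sin(phase);
# aw: trials x (Tw * n_fA) matrix of normalized amplitudes, columns ordered
# time-within-frequency so vector recycling of cw/sw aligns exactly.
.mvl_grid <- function(cw, sw, aw, n_fa) {
  n <- nrow(cw)
  x <- colSums(aw * as.vector(cw))
  y <- colSums(aw * as.vector(sw))
  colMeans(matrix(sqrt(x^2 + y^2), ncol = n_fa)) / n
}

# Segment-permuted copy of the data matrix (time x trials), with cuts drawn
# away from a margin at each end. In "common" mode one cut set is applied to
# all trials (row reindexing); in "per_trial" mode cuts are independent.
.surrogate_signals <- function(Xt, margin, n_segments, mode = "common") {
  nt <- nrow(Xt)
  lo <- margin + 1L
  hi <- nt - margin - 1L
  if (hi <= lo) { lo <- 2L; hi <- nt - 2L }  # degenerate margin fallback
  if (mode == "common") {
    ord <- segment_swap(seq_len(nt), sample(lo:hi, n_segments - 1L))
    return(Xt[ord, , drop = FALSE])
  }
  Xs <- Xt
  for (tr in seq_len(ncol(Xt))) {
    cuts <- sample(lo:hi, n_segments - 1L)
    Xs[, tr] <- segment_swap(Xt[, tr], cuts)
  }
  Xs
}

# Full PAC computation: observed and surrogate MVL over the fP x fA grid for
# one or more windows, sharing wavelet plans and surrogate signals.
.pac_engine <- function(ensemble, params, windows, keep_surrogates = FALSE) {
  stopifnot(inherits(ensemble, "trial_ensemble"), inherits(params, "pac_params"))
  times <- ensemble$times_s
  fs <- ensemble$sampling_rate_hz
  nt <- length(times)
  ntr <- nrow(ensemble$data)
  if (ntr < 2) stop("PAC requires at least 2 trials")
  fP <- params$fP_grid; fA <- params$fA_grid
  nfP <- length(fP); nfA <- length(fA)

  win_s <- lapply(windows, function(w) switch(w,
    stimulus = params$stim_window_s,
    baseline = params$baseline_window_s,
    stop("unknown window tag: ", w)))
  names(win_s) <- windows
  win_idx <- lapply(win_s, function(w) window_index(times, w))
  if (any(vapply(win_idx, length, 1L) < 3))
    stop("analysis window shorter than 3 samples")

  plan_fP <- .morlet_plan(nt, fs, fP, params$n_cycles)
  plan_fA <- .morlet_plan(nt, fs, fA, params$n_cycles)
  Xt <- t(ensemble$data)                     # time x trials

  # normalized amplitudes per fA, packed per window as trials x (Tw * nfA)
  norm_idx <- window_index(times, params$normalization_window_s)
  amp_fa <- .morlet_apply(plan_fA, Xt)
  aw <- lapply(win_idx, function(idx) matrix(0, ntr, length(idx) * nfA))
  for (j in seq_len(nfA)) {
    a <- minmax_normalize(t(Mod(amp_fa[[j]]))[, norm_idx, drop = FALSE])
    full <- matrix(0, ntr, nt)
    full[, norm_idx] <- a
    for (w in windows) {
      idx <- win_idx[[w]]
      aw[[w]][, (j - 1L) * length(idx) + seq_along(idx)] <- full[, idx]
    }
  }
  rm(amp_fa)

  phase_cs <- function(coef_list, idx) {
    lapply(coef_list, function(cf) {
      u <- cf[idx, , drop = FALSE]
      m <- Mod(u)
      u <- u / ifelse(m > 0, m, 1)
      list(c = t(Re(u)), s = t(Im(u)))
    })
  }

  obs_ph <- .morlet_apply(plan_fP, Xt)
  observed <- lapply(windows, function(w) {
    ph <- phase_cs(obs_ph, win_idx[[w]])
    out <- matrix(0, nfP, nfA, dimnames = list(fP, fA))
    for (p in seq_len(nfP))
      out[p, ] <- .mvl_grid(ph[[p]]$c, ph[[p]]$s, aw[[w]], nfA)
    out
  })
  names(observed) <- windows
  rm(obs_ph)

  # surrogates: segment-permute the raw signal, re-extract fP phase, keep
  # the unshuffled amplitudes
  margin <- round(morlet_sigma(min(fP), params$n_cycles) * fs)
  surr <- lapply(windows, function(w) array(0, c(params$n_surrogates, nfP, nfA)))
  names(surr) <- windows
  with_local_seed(params$seed, {
    for (s in seq_len(params$n_surrogates)) {
      Xs <- .surrogate_signals(Xt, margin, params$surrogate_segments,
                               params$surrogate_mode)
      ph_s <- .morlet_apply(plan_fP, Xs)
      for (w in windows) {
        ph <- phase_cs(ph_s, win_idx[[w]])
        for (p in seq_len(nfP))
          surr[[w]][s, p, ] <- .mvl_grid(ph[[p]]$c, ph[[p]]$s, aw[[w]], nfA)
      }
    }
  })

  out <- lapply(windows, function(w) {
    mu <- apply(surr[[w]], c(2, 3), mean)
    sdv <- apply(surr[[w]], c(2, 3), stats::sd)
    if (any(sdv == 0)) stop("degenerate surrogate distribution (sd = 0)")
    structure(list(values = (observed[[w]] - mu) / sdv,
                   raw_mvl = observed[[w]],
                   surrogate_mean = mu, surrogate_sd = sdv,
                   surrogates = if (keep_surrogates) surr[[w]] else NULL,
                   fP_grid = fP, fA_grid = fA,
                   kind = "surrogate_z", window = w,
                   window_s = win_s[[w]],
                   n_surrogates = params$n_surrogates,
                   n_trials = ntr, seed = params$seed),
              class = "comodulogram")
  })
  names(out) <- windows
  out
}

#' Surrogate-z comodulogram
#'
#' Computes the z-scored mean-vector-length PAC over the full fP x fA grid
#' for the requested window(s). For every cell, the observed across-trials
#' MVL (on min-max normalized fA amplitude and fP phase, both from Morlet
#' wavelet transforms) is z-scored against `n_surrogates` segment-swap
#' surrogates in which the phase stream is re-extracted from a
#' segment-permuted copy of the raw signal while the amplitudes stay fixed.
#' Requesting both windows at once shares the wavelet transforms and the
#' surrogate signals between them.
#'
#' @param ensemble A preprocessed [trial_ensemble()].
#' @param params A [pac_params()].
#' @param window "stimulus", "baseline", or both.
#' @param keep_surrogates Keep the full surrogate MVL arrays on the result.
#' @return A `comodulogram` object (single window) or a named list of them.
#' @export
comodulogram <- function(ensemble, params = pac_params(),
                         window = c("stimulus", "baseline"),
                         keep_surrogates = FALSE) {
  window <- match.arg(window, several.ok = TRUE)
  res <- .pac_engine(ensemble, params, window, keep_surrogates)
  if (length(window) == 1) res[[1]] else res
}

#' Surrogate MVL distribution for one comodulogram cell
#'
#' Runs the segment-swap surrogate procedure for a single (fP, fA) pair and
#' returns the raw surrogate MVL values together with the observed MVL.
#'
#' @param ensemble A [trial_ensemble()].
#' @param fP,fA Phase and amplitude frequencies (Hz).
#' @param params A [pac_params()] supplying windows, cycles, surrogate count
#'   and seed (its grids are ignored).
#' @param window "stimulus" or "baseline".
#' @return A list with `observed` (raw MVL) and `surrogates` (vector of
#'   `n_surrogates` raw MVL values).
#' @export
surrogate_pac <- function(ensemble, fP, fA, params = pac_params(),
                          window = "stimulus") {
  window <- match.arg(window, c("stimulus", "baseline"))
  params$fP_grid <- fP
  params$fA_grid <- fA
  res <- .pac_engine(ensemble, params, window, keep_surrogates = TRUE)[[1]]
  list(observed = res$raw_mvl[1, 1], surrogates = as.vector(res$surrogates))
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %s window [%g, %g) s, %d x %d grid (fP %g-%g, fA %g-%g Hz), %s, %d surrogates\n",
              x$window, x$window_s[1], x$window_s[2],
              length(x$fP_grid), length(x$fA_grid),
              min(x$fP_grid), max(x$fP_grid), min(x$fA_grid), max(x$fA_grid),
              x$kind, x$n_surrogates))
  pk <- arrayInd(which.max(x$values), dim(x$values))
  cat(sprintf("  peak z = %.2f at (fP = %g, fA = %g)\n",
              max(x$values), x$fP_grid[pk[1]], x$fA_grid[pk[2]]))
  invisible(x)
}
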