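#' Analysis window set
#'
#' The standard windows used throughout the pipeline, in seconds relative to
#' stimulus onset. All windows are half-open `[start, end)` and must lie
#' within the epoch.
#'
#' @param epoch_s Epoch limits.
#' @param amp_baseline_s Baseline window for amplitude correction and
#'   baseline-mean subtraction.
#' @param pac_baseline_s Baseline window for PAC estimation.
#' @param pac_stim_s Steady-state (stimulus) window for PAC estimation.
#' @param normalization_s Window over which min-max amplitude normalization
#'   is computed.
#' @return An object of class `window_set`.
#' @export
window_set <- function(epoch_s = c(-1.5, 1.5),
                       amp_baseline_s = c(-1.3, -0.5),
                       pac_baseline_s = c(-1.3, -0.5),
                       pac_stim_s = c(0.2, 1.0),
                       normalization_s = c(-1.3, 1.3)) {
  ws <- list(epoch_s = epoch_s, amp_baseline_s = amp_baseline_s,
             pac_baseline_s = pac_baseline_s, pac_stim_s = pac_stim_s,
             normalization_s = normalization_s)
  for (nm in names(ws)) {
    w <- ws[[nm]]
    if (length(w) != 2 || w[1] >= w[2])
      stop(nm, " must be an increasing (start, end) pair")
    if (nm != "epoch_s" && (w[1] < epoch_s[1] || w[2] > epoch_s[2]))
      stop(nm, " must lie within epoch_s")
  }
  structure(ws, class = "window_set")
}

#' Baseline mean subtraction
#'
#' Subtracts, per trial, the mean of the baseline-window samples. By default
#' the mean is removed from the entire epoch so that baseline-window
#' statistics downstream are centered; `scope = "poststim"` restricts the
#' subtraction to samples at `t >= 0`.
#'
#' @param ensemble A [trial_ensemble()].
#' @param window Baseline window `(start, end)` in seconds, half-open.
#' @param scope Either "epoch" (default) or "poststim".
#' @return The baseline-subtracted `trial_ensemble`.
#' @export
baseline_subtract <- function(ensemble, window = c(-1.3, -0.5),
                              scope = c("epoch", "poststim")) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  scope <- match.arg(scope)
  idx <- window_index(ensemble$times_s, window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  mu <- rowMeans(ensemble$data[, idx, drop = FALSE])
  if (scope == "epoch") {
    ensemble$data <- ensemble$data - mu
  } else {
    post <- ensemble$times_s >= 0
    ensemble$data[, post] <- ensemble$data[, post, drop = FALSE] - mu
  }
  ensemble
}

#' Peak-to-peak epoch rejection
#'
#' Drops every trial whose peak-to-peak amplitude (max minus min over the
#' whole epoch) reaches the threshold: a trial is rejected iff
#' `ptp >= ptp_threshold`. For source-level synthetic data the threshold is
#' in the data's arbitrary units; channel-level thresholds (e.g. fT for
#' magnetometers) apply when the data are in those units.
#'
#' @param ensemble A [trial_ensemble()].
#' @param ptp_threshold Positive rejection threshold.
#' @return A list with `ensemble` (retained trials) and `report`, a data.frame
#'   with one row per input trial: `trial_index`, `ptp`, `threshold`,
#'   `dropped`.
#' @export
reject_epochs <- function(ensemble, ptp_threshold) {
  stopifnot(inherits(ensemble, "trial_ensemble"), ptp_threshold > 0)
  ptp <- apply(ensemble$data, 1, function(x) max(x) - min(x))
  dropped <- ptp >= ptp_threshold
  report <- data.frame(trial_index = seq_along(ptp), ptp = ptp,
                       threshold = ptp_threshold, dropped = dropped)
  if (all(dropped)) {
    err <- structure(class = c("all_epochs_rejected", "error", "condition"),
                     list(message = "all trials exceed the peak-to-peak threshold",
                          call = sys.call(), report = report))
    stop(err)
  }
  list(ensemble = subset_trials(ensemble, which(!dropped)), report = report)
}

#' Keep only analysis (standard) trials
#'
#' Removes oddball trials, preserving trial order, per the paradigm rule that
#' oddball trials are excluded from analysis.
#'
#' @param ensemble A [trial_ensemble()] with `trial_kinds` set.
#' @return A `trial_ensemble` containing only standard trials.
#' @export
select_analysis_trials <- function(ensemble) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (is.null(ensemble$trial_kinds))
    stop("ensemble has no trial_kinds; cannot select analysis trials")
  keep <- which(ensemble$trial_kinds == "standard")
  if (length(keep) == 0) stop("no standard trials to retain")
  subset_trials(ensemble, keep)
}
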