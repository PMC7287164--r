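#' Construct a trial ensemble
#'
#' The basic data container of the pipeline: a trials x time matrix of
#' real-valued source-level (or channel-level) signal, with a uniform time
#' axis whose zero marks stimulus onset.
#'
#' @param data Numeric matrix, one row per trial, one column per sample.
#' @param times_s Numeric vector of sample times in seconds; must be strictly
#'   increasing with uniform spacing `1/sampling_rate_hz`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param condition_label Character label, e.g. "40Hz".
#' @param trial_kinds Character vector of "standard"/"oddball" per trial, or
#'   NULL if all trials are analysis trials.
#' @param ground_truth Optional list recording the generating specs and seed
#'   for synthetic data.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(data, times_s, sampling_rate_hz,
                           condition_label = NA_character_,
                           trial_kinds = NULL,
                           ground_truth = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("ensemble data must be finite numeric")
  if (length(times_s) != ncol(data))
    stop("times_s length must equal number of samples (columns)")
  dt <- diff(times_s)
  if (any(dt <= 0) || max(abs(dt - 1 / sampling_rate_hz)) > 1e-9)
    stop("times_s must be strictly increasing with spacing 1/sampling_rate_hz")
  if (!is.null(trial_kinds)) {
    if (length(trial_kinds) != nrow(data))
      stop("trial_kinds length must equal number of trials")
    if (!all(trial_kinds %in% c("standard", "oddball")))
      stop("trial_kinds must be 'standard' or 'oddball'")
  }
  structure(list(data = data,
                 times_s = as.numeric(times_s),
                 sampling_rate_hz = sampling_rate_hz,
                 condition_label = condition_label,
                 trial_kinds = trial_kinds,
                 ground_truth = ground_truth),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d trials x %d samples @ %g Hz, t in [%.3f, %.3f] s%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              min(x$times_s), max(x$times_s),
              if (!is.na(x$condition_label)) paste0(", condition ", x$condition_label) else ""))
  if (!is.null(x$trial_kinds))
    cat(sprintf("  kinds: %d standard, %d oddball\n",
                sum(x$trial_kinds == "standard"), sum(x$trial_kinds == "oddball")))
  invisible(x)
}

#' Number of trials in an ensemble
#' @param x A `trial_ensemble`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "trial_ensemble"))
  nrow(x$data)
}

#' Subset trials of an ensemble
#' @param x A `trial_ensemble`.
#' @param i Trial indices (row indices) to keep.
#' @return A `trial_ensemble` with the selected trials, order preserved.
#' @export
subset_trials <- function(x, i) {
  stopifnot(inherits(x, "trial_ensemble"))
  trial_ensemble(x$data[i, , drop = FALSE], x$times_s, x$sampling_rate_hz,
                 x$condition_label,
                 if (!is.null(x$trial_kinds)) x$trial_kinds[i] else NULL,
                 x$ground_truth)
}
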