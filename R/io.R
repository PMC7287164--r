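# Plain-text readers/writers: trials x time CSV with a JSON sidecar for
# metadata, comodulogram matrices as CSV, and study result directories.

#' Write a trial ensemble to CSV (+ JSON sidecar)
#'
#' The data matrix is written as CSV with one row per trial and columns named
#' by sample time; sampling rate, condition label, trial kinds and generator
#' provenance go to `<path>.json`.
#'
#' @param ensemble A [trial_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  m <- ensemble$data
  colnames(m) <- sprintf("t%.6f", ensemble$times_s)
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(sampling_rate_hz = ensemble$sampling_rate_hz,
               times_s = ensemble$times_s,
               condition_label = ensemble$condition_label,
               trial_kinds = ensemble$trial_kinds)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial ensemble from CSV
#'
#' Reads the trials x time matrix written by [write_ensemble_csv()], or any
#' delimited numeric file with one trial per row. If no JSON sidecar exists,
#' `sampling_rate_hz` and `t0_s` (time of the first sample) must be given.
#'
#' @param path CSV path.
#' @param sampling_rate_hz Sampling rate, if there is no sidecar.
#' @param t0_s Time of the first sample in seconds, if there is no sidecar.
#' @param condition_label Optional label override.
#' @return A [trial_ensemble()].
#' @export
read_ensemble_csv <- function(path, sampling_rate_hz = NULL, t0_s = NULL,
                              condition_label = NA_character_) {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  sidecar <- paste0(path, ".json")
  kinds <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sampling_rate_hz <- meta$sampling_rate_hz
    times <- meta$times_s
    if (is.na(condition_label) && !is.null(meta$condition_label) &&
        !is.na(meta$condition_label))
      condition_label <- meta$condition_label
    kinds <- meta$trial_kinds
  } else {
    if (is.null(sampling_rate_hz) || is.null(t0_s))
      stop("no JSON sidecar: sampling_rate_hz and t0_s are required")
    times <- t0_s + (seq_len(ncol(m)) - 1) / sampling_rate_hz
  }
  dimnames(m) <- NULL
  trial_ensemble(m, times, sampling_rate_hz, condition_label, kinds)
}

#' Write a comodulogram as a CSV matrix (+ JSON sidecar)
#'
#' fP in rows, fA in columns; window, seed and surrogate metadata in
#' `<path>.json`.
#'
#' @param comod A `comodulogram` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comodulogram_csv <- function(comod, path) {
  stopifnot(inherits(comod, "comodulogram"))
  m <- comod$values
  rownames(m) <- comod$fP_grid
  colnames(m) <- comod$fA_grid
  utils::write.csv(m, path, row.names = TRUE)
  jsonlite::write_json(list(kind = comod$kind, window = comod$window,
                            window_s = comod$window_s,
                            n_surrogates = comod$n_surrogates,
                            n_trials = comod$n_trials, seed = comod$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write study results to a directory
#'
#' Emits `subjects.csv` (per-subject summaries and cluster PAC values),
#' `clusters.csv` (the cluster table), `waveshape.csv` (rise-decay
#' comparisons), per-subject comodulogram CSVs under `comodulograms/`, and a
#' `manifest.json` recording seeds and parameters so every number is
#' recomputable.
#'
#' @param study An `assr_study` from [run_study()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "assr_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(study$cluster_test$clusters,
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  ws <- do.call(rbind, lapply(study$waveshape, function(w)
    data.frame(fP_hz = w$fP_hz, mean_stim_ratio = mean(w$stim_ratios),
               mean_base_ratio = mean(w$base_ratios), t = w$t, df = w$df,
               p_corrected = w$p_corrected)))
  if (!is.null(ws))
    utils::write.csv(ws, file.path(out_dir, "waveshape.csv"), row.names = FALSE)
  if (!is.null(study$confounds))
    utils::write.csv(study$confounds, file.path(out_dir, "confounds.csv"),
                     row.names = FALSE)
  cdir <- file.path(out_dir, "comodulograms")
  dir.create(cdir, showWarnings = FALSE)
  for (i in seq_along(study$comodulograms)) {
    sid <- study$subjects$subject[i]
    write_comodulogram_csv(study$comodulograms[[i]]$stimulus,
                           file.path(cdir, paste0(sid, "_stimulus.csv")))
    write_comodulogram_csv(study$comodulograms[[i]]$baseline,
                           file.path(cdir, paste0(sid, "_baseline.csv")))
  }
  p <- study$params
  manifest <- list(seed = study$seed,
                   n_subjects = p$n_subjects, n_trials = p$n_trials,
                   null_cohort = p$null_cohort,
                   paradigm = unclass(p$spec),
                   coupling = unclass(p$coupling),
                   noise = unclass(p$noise),
                   pac = unclass(p$pac),
                   cluster = unclass(p$cluster))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a session plan to CSV
#'
#' @param plan Data frame from [generate_session_plan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_plan_csv <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE)
  invisible(path)
}
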