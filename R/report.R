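#' Mean PAC over a cluster's cells
#'
#' Summarizes a subject's comodulogram over the cells of a cluster found by
#' [cluster_permutation_test()]: the arithmetic mean of the z values over the
#' member cells. Applied to the stimulus and baseline comodulograms (and
#' their difference) this yields the per-subject cluster coupling strengths
#' used for group-level comparison.
#'
#' @param comod A `comodulogram` object or fP x fA matrix.
#' @param cells Two-column index matrix of cluster member cells.
#' @return Scalar mean z over the cluster.
#' @export
cluster_pac_values <- function(comod, cells) {
  v <- if (inherits(comod, "comodulogram")) comod$values else as.matrix(comod)
  cells <- as.matrix(cells)
  if (nrow(cells) == 0) stop("empty cluster")
  mean(v[cells])
}

#' Amplitude-confound check on cluster PAC values
#'
#' Spearman rank correlation of per-subject cluster PAC values against
#' per-subject signal-amplitude summaries (for the fA band and the fP band),
#' to measure any residual influence of raw amplitude on coupling strength
#' after min-max normalization and z-scoring.
#'
#' @param pac_values Per-subject cluster PAC values (length >= 5).
#' @param amplitude_values Per-subject amplitude summaries, same length.
#' @return A list with `rho`, `p`, `n`.
#' @export
amplitude_confound_correlation <- function(pac_values, amplitude_values) {
  stopifnot(length(pac_values) == length(amplitude_values))
  n <- length(pac_values)
  if (n < 5) stop("need at least 5 paired observations")
  if (stats::sd(pac_values) == 0 || stats::sd(amplitude_values) == 0)
    stop("constant input; rank correlation undefined")
  ct <- stats::cor.test(pac_values, amplitude_values, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Run the full synthetic ASSR coupling study
#'
#' End-to-end driver: generates a cohort, preprocesses each subject's epochs
#' (baseline subtraction, optional peak-to-peak rejection, oddball exclusion),
#' computes per-subject entrainment summaries (stimulation-band amplitude and
#' ITC), stimulus and baseline comodulograms, the across-subject cluster
#' permutation test, rise-decay waveform controls at the cluster phase
#' frequencies, and amplitude-confound correlations. Writes tidy result
#' tables if `out_dir` is given.
#'
#' @param spec A [paradigm_spec()].
#' @param coupling A [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param pac A [pac_params()].
#' @param cluster A [cluster_test_params()].
#' @param n_subjects Number of synthetic subjects.
#' @param n_trials Analysis trials per subject.
#' @param seed Master seed; the whole study is reproducible from it.
#' @param ptp_threshold Optional peak-to-peak rejection threshold (data
#'   units); NULL skips rejection.
#' @param null_cohort Generate an exchangeable null cohort (no coupling, no
#'   entrained response).
#' @param out_dir Optional output directory for `subjects.csv`,
#'   `clusters.csv`, `comodulograms/` and `manifest.json`.
#' @return An object of class `assr_study`: `subjects` (per-subject summary
#'   data.frame), `cluster_test`, `comodulograms` (per subject, stimulus and
#'   baseline), `waveshape`, `confounds`, `seed`, `params`.
#' @export
run_study <- function(spec = paradigm_spec(),
                      coupling = coupling_spec(),
                      noise = noise_spec(),
                      pac = pac_params(),
                      cluster = cluster_test_params(),
                      n_subjects = 12,
                      n_trials = spec$n_trials_total - spec$n_oddball,
                      seed = 1L,
                      ptp_threshold = NULL,
                      null_cohort = FALSE,
                      out_dir = NULL) {
  seeds <- derive_seeds(seed, 2)
  cohort <- generate_cohort(n_subjects, spec, coupling, noise,
                            n_trials = n_trials, seed = seeds[1],
                            null_cohort = null_cohort)
  pac$seed <- seeds[2]
  cluster$seed <- seeds[2]

  stim_band <- spec$stim_freq_hz + c(-1, 1)
  amp_params <- wavelet_params(sort(unique(c(stim_band[1]:stim_band[2],
                                             pac$fP_grid, pac$fA_grid))),
                               pac$n_cycles)

  comods <- vector("list", n_subjects)
  subj_rows <- vector("list", n_subjects)
  tf_cache <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ens <- cohort[[i]]
    if (!is.null(ens$trial_kinds)) ens <- select_analysis_trials(ens)
    ens <- baseline_subtract(ens)
    if (!is.null(ptp_threshold)) ens <- reject_epochs(ens, ptp_threshold)$ensemble

    dec <- morlet_transform(ens, amp_params)
    amp <- tf_amplitude(dec)
    phc <- itc(dec)
    tf_cache[[i]] <- list(amp = amp, itc = phc, ensemble = ens)
    comods[[i]] <- comodulogram(ens, pac, window = c("stimulus", "baseline"))

    subj_rows[[i]] <- data.frame(
      subject = names(cohort)[i],
      condition = ens$condition_label,
      n_trials = n_trials(ens),
      assr_amplitude = band_summary(amp, stim_band, pac$stim_window_s),
      assr_itc = band_summary(phc, stim_band, pac$stim_window_s),
      fA_amplitude = band_summary(amp, range(pac$fA_grid), pac$stim_window_s),
      fP_amplitude = band_summary(amp, range(pac$fP_grid), pac$stim_window_s))
  }
  subjects <- do.call(rbind, subj_rows)

  ct <- cluster_permutation_test(lapply(comods, `[[`, "stimulus"),
                                 lapply(comods, `[[`, "baseline"),
                                 cluster)
  sig <- which(ct$clusters$significant)

  # per-subject cluster PAC values (stimulus, baseline, difference)
  for (k in seq_along(ct$cluster_cells)) {
    cells <- ct$cluster_cells[[k]]
    s <- vapply(comods, function(cm) cluster_pac_values(cm$stimulus, cells), 1)
    b <- vapply(comods, function(cm) cluster_pac_values(cm$baseline, cells), 1)
    subjects[[paste0("cluster", k, "_stim")]] <- s
    subjects[[paste0("cluster", k, "_base")]] <- b
    subjects[[paste0("cluster", k, "_diff")]] <- s - b
  }

  # waveform-shape control at the phase frequencies of significant clusters
  # (all fP grid frequencies if none)
  ws_fp <- if (length(sig))
    sort(unique(unlist(lapply(sig, function(k)
      pac$fP_grid[unique(ct$cluster_cells[[k]][, 1])]))))
  else pac$fP_grid
  waveshape <- lapply(ws_fp, function(fp) {
    sr <- vapply(tf_cache, function(tc)
      rise_decay_ratio(tc$ensemble, fp, pac$stim_window_s)$ratio, 1)
    br <- vapply(tf_cache, function(tc)
      rise_decay_ratio(tc$ensemble, fp, pac$baseline_window_s)$ratio, 1)
    c(list(fP_hz = fp, stim_ratios = sr, base_ratios = br),
      compare_rise_decay(sr, br, n_comparisons = length(ws_fp)))
  })

  confounds <- NULL
  if (length(sig) && n_subjects >= 5) {
    confounds <- do.call(rbind, lapply(sig, function(k) {
      rbind(
        data.frame(cluster_id = k, window = "stimulus", amplitude_band = "fA",
                   t(unlist(amplitude_confound_correlation(
                     subjects[[paste0("cluster", k, "_stim")]],
                     subjects$fA_amplitude)))),
        data.frame(cluster_id = k, window = "stimulus", amplitude_band = "fP",
                   t(unlist(amplitude_confound_correlation(
                     subjects[[paste0("cluster", k, "_stim")]],
                     subjects$fP_amplitude)))))
    }))
  }

  study <- structure(list(subjects = subjects, cluster_test = ct,
                          comodulograms = comods, waveshape = waveshape,
                          confounds = confounds, seed = seed,
                          params = list(spec = spec, coupling = coupling,
                                        noise = noise, pac = pac,
                                        cluster = cluster,
                                        n_subjects = n_subjects,
                                        n_trials = n_trials,
                                        null_cohort = null_cohort)),
                     class = "assr_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.assr_study <- function(x, ...) {
  cat(sprintf("<assr_study> %d subjects, condition %s, seed %s\n",
              nrow(x$subjects), x$subjects$condition[1], format(x$seed)))
  print(x$cluster_test)
  invisible(x)
}
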