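#' Familywise error calibration of the cluster permutation test
#'
#' Validity check for the full stimulus-vs-baseline pipeline: simulates
#' cohorts in which the stimulus and baseline windows are draws from the
#' identical no-coupling generative process (stationary background, no
#' entrained response, zero modulation depth), runs the per-subject
#' comodulograms and the across-subject cluster permutation test on each
#' cohort, and reports how often any cluster is declared significant. Under
#' this exchangeable null the familywise false-positive rate should not
#' exceed the configured `cluster_alpha`.
#'
#' @param n_cohorts Number of simulated null cohorts.
#' @param n_subjects Subjects per cohort.
#' @param spec A [paradigm_spec()] (sampling rate and epoch geometry).
#' @param coupling A [coupling_spec()]; modulation and entrainment are forced
#'   off regardless.
#' @param noise A [noise_spec()]; entrained amplitude is forced to 0.
#' @param pac A [pac_params()] defining the comodulogram grid and surrogates.
#' @param cluster A [cluster_test_params()].
#' @param n_trials Trials per subject.
#' @param seed Master seed; cohorts use derived seeds.
#' @return A list with `false_positive` (logical per cohort),
#'   `rate` (fraction with any significant cluster), `n_cohorts`, and
#'   `n_clusters` (count of significant clusters per cohort).
#' @export
null_fwer_simulation <- function(n_cohorts, n_subjects = 12,
                                 spec = paradigm_spec(),
                                 coupling = coupling_spec(),
                                 noise = noise_spec(),
                                 pac = pac_params(),
                                 cluster = cluster_test_params(),
                                 n_trials = 16, seed = 1L) {
  seeds <- derive_seeds(seed, 2 * n_cohorts)
  fp <- logical(n_cohorts)
  ncl <- integer(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    cohort <- generate_cohort(n_subjects, spec, coupling, noise,
                              n_trials = n_trials, seed = seeds[2 * k - 1],
                              null_cohort = TRUE)
    pac$seed <- seeds[2 * k]
    cluster$seed <- seeds[2 * k]
    comods <- lapply(cohort, function(ens)
      comodulogram(baseline_subtract(ens), pac,
                   window = c("stimulus", "baseline")))
    ct <- cluster_permutation_test(lapply(comods, `[[`, "stimulus"),
                                   lapply(comods, `[[`, "baseline"),
                                   cluster)
    ncl[k] <- sum(ct$clusters$significant)
    fp[k] <- ncl[k] > 0
  }
  list(false_positive = fp, rate = mean(fp), n_cohorts = n_cohorts,
       n_clusters = ncl)
}
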