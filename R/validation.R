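#' Frequency-recovery study on synthetic triplicate experiments
#'
#' Repeatedly generates replicate filter experiments at a known true transfer
#' frequency (count level: per-field Poisson transconjugant counts, no image
#' rendering), estimates the frequency per replicate, aggregates replicates,
#' and checks whether the replicate mean lies within `k_sem` standard errors
#' of the truth.
#'
#' @param true_frequency true transfer frequency (T/R).
#' @param geometry an [experiment_geometry()].
#' @param n_repeats number of independent repetitions.
#' @param n_replicates replicate filters per repetition.
#' @param k_sem coverage multiple of the sample SEM.
#' @param seed integer seed.
#' @return List with `results` (data.frame: repeat_id, mean, sem, covered),
#'   `coverage` (fraction covered) and `mean_estimate`.
#' @export
frequency_recovery_study <- function(true_frequency = 1e-4,
                                     geometry = experiment_geometry(),
                                     n_repeats = 100,
                                     n_replicates = 3,
                                     k_sem = 3,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(2147483647L, n_repeats * n_replicates),
                      nrow = n_repeats)
  rows <- lapply(seq_len(n_repeats), function(i) {
    freqs <- vapply(seq_len(n_replicates), function(r) {
      ex <- generate_filter_experiment(true_frequency, geometry,
                                       seed = rep_seeds[i, r], render = FALSE)
      transfer_frequency(ex$total_true, geometry)
    }, numeric(1))
    est <- aggregate_replicates(freqs)
    data.frame(repeat_id = i, mean = est$mean, sem = est$sem,
               covered = is.finite(est$sem) &&
                 abs(est$mean - true_frequency) <= k_sem * est$sem)
  })
  results <- do.call(rbind, rows)
  list(results = results,
       coverage = mean(results$covered),
       mean_estimate = mean(results$mean))
}

#' Retromobilization-probability recovery study
#'
#' Runs the mating simulator over many seeds at a known
#' `p_mob_given_conj` and recovers the retromobilization probability from
#' the realized intrastrain frequencies through the mobilization calculus.
#'
#' @param n_seeds number of simulation seeds.
#' @param n_recipients recipients per mating.
#' @param p_conj per-contact conjugal transfer probability (intrastrain
#'   scale).
#' @param p_mob_given_conj true mobilization probability.
#' @param permissive_fraction,mobilizer_fraction community parameters for the
#'   community-side matings.
#' @param seed master seed.
#' @return List with `p_retro` (per-seed recovered values, `NA` where
#'   recovery was skipped on a zero divisor), `median`, `n_skipped`.
#' @export
p_retro_recovery_study <- function(n_seeds = 100,
                                   n_recipients = 1e6,
                                   p_conj = 1.76e-3,
                                   p_mob_given_conj = 0.474,
                                   permissive_fraction = 0.066,
                                   mobilizer_fraction = 0.05,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483647L, n_seeds)
  p_retro <- vapply(seeds, function(s) {
    rec <- recover_parameters(n_recipients, permissive_fraction,
                              mobilizer_fraction, p_conj, p_mob_given_conj,
                              seed = s)
    if (rec$skipped) NA_real_ else rec$report$p_retro
  }, numeric(1))
  list(p_retro = p_retro,
       median = stats::median(p_retro, na.rm = TRUE),
       n_skipped = sum(is.na(p_retro)))
}
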