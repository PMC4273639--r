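#' Parameters of the stochastic mating simulator
#'
#' A well-mixed single-contact Bernoulli model of the three plasmid-transfer
#' mechanisms: conjugation of a self-transmissible plasmid, direct
#' mobilization of a mobilizable plasmid by a co-resident conjugal plasmid,
#' and two-step retromobilization (the recipient's conjugal plasmid first
#' transfers into the donor, then mobilizes the donor's mobilizable plasmid
#' back). Each recipient experiences at most one observable event, matching
#' microcolony-based quantification.
#'
#' @param n_recipients number of recipients (>= 1).
#' @param permissive_fraction probability a recipient can receive and
#'   maintain the conjugal plasmid.
#' @param mobilizer_fraction probability a recipient carries a compatible
#'   mobilizing conjugal plasmid.
#' @param p_conj probability of conjugal transfer per permissive
#'   donor-recipient contact.
#' @param p_mob_given_conj probability the mobilizable plasmid transfers once
#'   a conjugal plasmid is co-resident in the donor.
#' @param donor_carries_mobilizer `TRUE` for the direct-mobilization
#'   scenario (donor co-hosts conjugal + mobilizable plasmid).
#' @param seed integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_recipients,
                       permissive_fraction = 1,
                       mobilizer_fraction = 1,
                       p_conj,
                       p_mob_given_conj = 0,
                       donor_carries_mobilizer = FALSE,
                       seed = 1L) {
  probs <- c(permissive_fraction = permissive_fraction,
             mobilizer_fraction = mobilizer_fraction,
             p_conj = p_conj, p_mob_given_conj = p_mob_given_conj)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (n_recipients < 1) stop("n_recipients must be at least 1")
  structure(list(n_recipients = as.double(n_recipients),
                 permissive_fraction = permissive_fraction,
                 mobilizer_fraction = mobilizer_fraction,
                 p_conj = p_conj,
                 p_mob_given_conj = p_mob_given_conj,
                 donor_carries_mobilizer = donor_carries_mobilizer,
                 seed = as.integer(seed)),
            class = "sim_params")
}

sim_outcome <- function(params, n_conj = 0, n_retro = 0, n_direct = 0,
                        n_step1 = NA_real_) {
  events <- max(n_conj, n_retro, n_direct)
  structure(list(n_conjugation_events = n_conj,
                 n_retro_events = n_retro,
                 n_direct_events = n_direct,
                 n_step1_successes = n_step1,
                 frequency = events / params$n_recipients,
                 n_recipients = params$n_recipients,
                 seed = params$seed),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf(
    "sim_outcome: conj %g, retro %g, direct %g of %g recipients (frequency %s T/R)\n",
    x$n_conjugation_events, x$n_retro_events, x$n_direct_events,
    x$n_recipients, signif(x$frequency, 3)))
  invisible(x)
}

#' Simulate conjugation of a self-transmissible plasmid
#'
#' Each recipient independently becomes a transconjugant with probability
#' `permissive_fraction * p_conj`; the event count is Binomial.
#'
#' @param params a [sim_params()].
#' @return A `sim_outcome` with `n_conjugation_events` and the realized
#'   frequency (events per recipient).
#' @export
simulate_conjugation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params$permissive_fraction * params$p_conj
  n <- stats::rbinom(1, params$n_recipients, p)
  sim_outcome(params, n_conj = n)
}

#' Simulate two-step retromobilization
#'
#' Step 1: a recipient's conjugal plasmid reaches the donor with probability
#' `mobilizer_fraction * p_conj`. Step 2: given step 1, the donor's
#' mobilizable plasmid transfers back with probability `p_mob_given_conj`.
#' A retromobilization event requires both, so retro events are a binomial
#' thinning of the step-1 successes and can never exceed them.
#'
#' @param params a [sim_params()] with `donor_carries_mobilizer = FALSE`
#'   (the donor carries only the mobilizable plasmid).
#' @return A `sim_outcome` with `n_retro_events`, `n_step1_successes` and the
#'   realized retro frequency.
#' @export
simulate_retromobilization <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (isTRUE(params$donor_carries_mobilizer))
    stop("retromobilization assumes the donor does not carry a mobilizing conjugal plasmid")
  set.seed(params$seed)
  p1 <- params$mobilizer_fraction * params$p_conj
  n_step1 <- stats::rbinom(1, params$n_recipients, p1)
  n_retro <- stats::rbinom(1, n_step1, params$p_mob_given_conj)
  sim_outcome(params, n_retro = n_retro, n_step1 = n_step1)
}

#' Simulate direct mobilization
#'
#' The donor co-hosts the mobilizable and the mobilizing conjugal plasmid;
#' the conjugal machinery establishes the pilus in one step, so each
#' recipient receives the mobilizable plasmid with probability
#' `permissive_fraction * p_conj * p_mob_given_conj`.
#'
#' @param params a [sim_params()] with `donor_carries_mobilizer = TRUE`.
#' @return A `sim_outcome` with `n_direct_events`.
#' @export
simulate_direct_mobilization <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!isTRUE(params$donor_carries_mobilizer))
    stop("direct mobilization requires donor_carries_mobilizer = TRUE")
  set.seed(params$seed)
  p <- params$permissive_fraction * params$p_conj * params$p_mob_given_conj
  n <- stats::rbinom(1, params$n_recipients, p)
  sim_outcome(params, n_direct = n)
}

#' Simulate the four-mating panel used by the mobilization calculus
#'
#' Runs the community and intrastrain matings with one call each:
#' conjugal plasmid into the community (`conj_comm`), conjugal plasmid
#' intrastrain (`conj_intra`, permissive fraction 1), mobilizable plasmid
#' into the community via retromobilization (`retro_comm`), mobilizable
#' plasmid intrastrain with a mobilizer-carrying recipient (`retro_intra`,
#' mobilizer fraction 1), plus optionally direct mobilization into the
#' community (`direct_comm`).
#'
#' @param n_recipients recipients per mating.
#' @param permissive_fraction community fraction permissive to the conjugal
#'   plasmid.
#' @param mobilizer_fraction community fraction carrying a compatible
#'   mobilizing conjugal plasmid.
#' @param p_conj per-contact conjugal transfer probability.
#' @param p_mob_given_conj mobilization probability given a co-resident
#'   conjugal plasmid.
#' @param seed integer seed (each mating uses a seed derived from it).
#' @param include_direct also simulate the direct-mobilization mating.
#' @return A [mating_frequency_set()] of realized frequencies, with the
#'   outcome objects attached as attribute `outcomes`.
#' @export
simulate_mating_panel <- function(n_recipients,
                                  permissive_fraction,
                                  mobilizer_fraction,
                                  p_conj,
                                  p_mob_given_conj,
                                  seed = 1L,
                                  include_direct = TRUE) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483647L, 5)
  out <- list(
    conj_comm = simulate_conjugation(sim_params(
      n_recipients, permissive_fraction = permissive_fraction,
      p_conj = p_conj, seed = seeds[1])),
    conj_intra = simulate_conjugation(sim_params(
      n_recipients, permissive_fraction = 1, p_conj = p_conj,
      seed = seeds[2])),
    retro_comm = simulate_retromobilization(sim_params(
      n_recipients, mobilizer_fraction = mobilizer_fraction,
      p_conj = p_conj, p_mob_given_conj = p_mob_given_conj,
      seed = seeds[3])),
    retro_intra = simulate_retromobilization(sim_params(
      n_recipients, mobilizer_fraction = 1, p_conj = p_conj,
      p_mob_given_conj = p_mob_given_conj, seed = seeds[4])))
  if (include_direct)
    out$direct_comm <- simulate_direct_mobilization(sim_params(
      n_recipients, permissive_fraction = permissive_fraction,
      p_conj = p_conj, p_mob_given_conj = p_mob_given_conj,
      donor_carries_mobilizer = TRUE, seed = seeds[5]))
  freqs <- mating_frequency_set(
    conj_comm = out$conj_comm$frequency,
    conj_intra = out$conj_intra$frequency,
    retro_comm = out$retro_comm$frequency,
    retro_intra = out$retro_intra$frequency,
    direct_comm = if (include_direct) out$direct_comm$frequency else NA)
  attr(freqs, "outcomes") <- out
  freqs
}

#' Recover mobilization-calculus parameters from simulated matings
#'
#' Feeds the realized frequencies of a simulated mating panel into
#' [build_report()] and returns the report next to the simulation truth, for
#' parameter-recovery validation: the recovered retromobilization
#' probability should converge to the true `p_mob_given_conj` and the
#' recovered permissiveness equivalents to the true `permissive_fraction` as
#' `n_recipients` grows.
#'
#' @inheritParams simulate_mating_panel
#' @return List with `report` (a `mobilization_report`, or `NULL` with
#'   `skipped = TRUE` when a realized divisor frequency is zero), `freqs`,
#'   `truth` and `skipped`.
#' @export
recover_parameters <- function(n_recipients,
                               permissive_fraction,
                               mobilizer_fraction,
                               p_conj,
                               p_mob_given_conj,
                               seed = 1L) {
  freqs <- simulate_mating_panel(n_recipients, permissive_fraction,
                                 mobilizer_fraction, p_conj,
                                 p_mob_given_conj, seed = seed)
  truth <- list(permissive_fraction = permissive_fraction,
                mobilizer_fraction = mobilizer_fraction,
                p_conj = p_conj, p_mob_given_conj = p_mob_given_conj)
  divisors <- c(freq_of(freqs, "conj_intra"), freq_of(freqs, "retro_intra"),
                freq_of(freqs, "conj_comm"))
  if (any(divisors == 0))
    return(list(report = NULL, freqs = freqs, truth = truth, skipped = TRUE))
  list(report = build_report(freqs), freqs = freqs, truth = truth,
       skipped = FALSE)
}
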