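#' Set of mating transfer frequencies for the mobilization calculus
#'
#' Bundles the five transfer frequencies (T/R) the mobilization-potential
#' calculus consumes, each optionally with a standard error and the
#' per-replicate values it was aggregated from:
#'
#' * `conj_comm` - conjugal plasmid from the donor strain into the community.
#' * `conj_intra` - conjugal plasmid in an isogenic (intrastrain) mating.
#' * `retro_comm` - mobilizable plasmid into the community (retromobilization
#'   by the community's own conjugal plasmids).
#' * `retro_intra` - mobilizable plasmid into an isogenic recipient already
#'   carrying the mobilizing conjugal plasmid.
#' * `direct_comm` - mobilizable plasmid into the community from a donor
#'   co-hosting the mobilizing conjugal plasmid (direct mobilization).
#'
#' @param conj_comm,conj_intra,retro_comm,retro_intra,direct_comm transfer
#'   frequencies in T/R; each may be a bare number, a named list/vector with
#'   elements `mean` and optionally `sem`, or a [aggregate_replicates()]
#'   `frequency_estimate`. `NA` marks an unmeasured mating.
#' @return An object of class `mating_frequency_set`: a list of per-mating
#'   records with `mean`, `sem` and `per_replicate` fields.
#' @examples
#' mating_frequency_set(conj_comm = 1.16e-4, conj_intra = 1.76e-3,
#'                      retro_comm = 1.16e-5, retro_intra = 8.34e-4,
#'                      direct_comm = 3.14e-3)
#' @export
mating_frequency_set <- function(conj_comm = NA, conj_intra = NA,
                                 retro_comm = NA, retro_intra = NA,
                                 direct_comm = NA) {
  as_record <- function(x, role) {
    if (inherits(x, "frequency_estimate"))
      return(list(mean = x$mean, sem = x$sem, per_replicate = x$per_replicate))
    if (is.list(x) ||
        (is.numeric(x) && !is.null(names(x)) && "mean" %in% names(x))) {
      x <- as.list(x)
      rec <- list(mean = as.numeric(x$mean),
                  sem = if (is.null(x$sem)) NA_real_ else as.numeric(x$sem),
                  per_replicate = if (is.null(x$per_replicate)) NULL
                                  else as.numeric(x$per_replicate))
    } else {
      rec <- list(mean = unname(as.numeric(x)), sem = NA_real_,
                  per_replicate = NULL)
    }
    if (!is.na(rec$mean) && rec$mean < 0)
      stop(sprintf("frequency '%s' must be non-negative", role))
    if (!is.na(rec$sem) && rec$sem < 0)
      stop(sprintf("SEM of '%s' must be non-negative", role))
    rec
  }
  roles <- list(conj_comm = conj_comm, conj_intra = conj_intra,
                retro_comm = retro_comm, retro_intra = retro_intra,
                direct_comm = direct_comm)
  structure(Map(as_record, roles, names(roles)), class = "mating_frequency_set")
}

freq_of <- function(freqs, role) {
  stopifnot(inherits(freqs, "mating_frequency_set"))
  freqs[[role]]$mean
}

#' Community permissiveness in intrastrain equivalents
#'
#' Normalises the community transfer frequency of a conjugal plasmid by the
#' frequency of the same plasmid in an isogenic mating, removing donor-side
#' promiscuity and contact-saturation effects from the comparison.
#'
#' @param f_conj_comm community transfer frequency of the conjugal plasmid
#'   (T/R).
#' @param f_conj_intra intrastrain transfer frequency of the same plasmid
#'   (T/R), strictly positive.
#' @return Dimensionless permissiveness in intrastrain equivalents.
#' @examples
#' permissiveness_equivalents(1.16e-4, 1.76e-3)  # ~0.066
#' @export
permissiveness_equivalents <- function(f_conj_comm, f_conj_intra) {
  check_ratio_inputs(f_conj_comm, f_conj_intra, "f_conj_intra")
  f_conj_comm / f_conj_intra
}

#' Probability that a freshly acquired conjugal plasmid mobilizes the
#' mobilizable plasmid
#'
#' The intrastrain retromobilization frequency shares its first two steps
#' (conjugal transfer from recipient to donor) with the intrastrain conjugal
#' frequency; their ratio therefore estimates the conditional probability of
#' the subsequent mobilization step. As a ratio of measured frequencies it
#' can exceed 1; such values are returned with a warning rather than clamped,
#' since they indicate an assay anomaly worth surfacing.
#'
#' @param f_retro_intra intrastrain retromobilization frequency (T/R).
#' @param f_conj_intra intrastrain conjugal transfer frequency (T/R), > 0.
#' @return The retromobilization probability (dimensionless).
#' @examples
#' retromobilization_probability(8.34e-4, 1.76e-3)  # ~0.474
#' @export
retromobilization_probability <- function(f_retro_intra, f_conj_intra) {
  check_ratio_inputs(f_retro_intra, f_conj_intra, "f_conj_intra")
  p <- f_retro_intra / f_conj_intra
  if (p > 1)
    warning(sprintf("retromobilization probability %.3g exceeds 1; returned unclamped", p))
  p
}

#' Maximal mobilization potential of a community
#'
#' Corrects the observed community mobilization frequency for the probability
#' that an acquired conjugal plasmid actually performs the mobilization step:
#' the frequency that would be observed if every such opportunity were
#' realised.
#'
#' @param f_retro_comm community retromobilization frequency (T/R).
#' @param p_retro retromobilization probability, strictly positive.
#' @return Maximal mobilization potential in T/R.
#' @examples
#' maximal_mobilization_potential(1.16e-5, 0.474)  # ~2.45e-5
#' @export
maximal_mobilization_potential <- function(f_retro_comm, p_retro) {
  check_ratio_inputs(f_retro_comm, p_retro, "p_retro")
  f_retro_comm / p_retro
}

#' Maximal mobilization potential in permissiveness equivalents
#'
#' Expresses the maximal mobilization potential relative to the community's
#' permissiveness for the conjugal plasmid.
#'
#' @param m_max maximal mobilization potential (T/R).
#' @param f_conj_comm community transfer frequency of the conjugal plasmid
#'   (T/R), strictly positive.
#' @return Dimensionless mobilization potential in permissiveness equivalents.
#' @examples
#' mobilization_equivalents(2.45e-5, 1.16e-4)  # ~0.211
#' @export
mobilization_equivalents <- function(m_max, f_conj_comm) {
  check_ratio_inputs(m_max, f_conj_comm, "f_conj_comm")
  m_max / f_conj_comm
}

#' Fold changes of direct mobilization over retromobilization and
#' permissiveness
#'
#' @param freqs a [mating_frequency_set()] with `direct_comm`, `retro_comm`
#'   and `conj_comm` present; the two divisors must be positive.
#' @return Named list with `direct_vs_retro` (direct mobilization frequency
#'   over community retromobilization frequency) and
#'   `direct_vs_permissiveness` (over the community conjugal frequency).
#' @export
fold_changes <- function(freqs) {
  f_direct <- freq_of(freqs, "direct_comm")
  f_retro <- freq_of(freqs, "retro_comm")
  f_conj <- freq_of(freqs, "conj_comm")
  check_ratio_inputs(f_direct, f_retro, "retro_comm")
  check_ratio_inputs(f_direct, f_conj, "conj_comm")
  list(direct_vs_retro = f_direct / f_retro,
       direct_vs_permissiveness = f_direct / f_conj)
}

check_ratio_inputs <- function(num, den, den_name) {
  if (is.na(num) || is.na(den))
    stop("missing frequency input", call. = FALSE)
  if (num < 0) stop("numerator frequency must be non-negative", call. = FALSE)
  if (den <= 0)
    stop(sprintf("%s must be strictly positive", den_name), call. = FALSE)
  invisible(TRUE)
}

#' Delta-method standard deviation of a ratio
#'
#' First-order propagation for r = a/b:
#' sd(r) = r * sqrt((sa/a)^2 + (sb/b)^2).
#'
#' @param a,b numerator and denominator (b > 0, a != 0 unless sa = 0).
#' @param sa,sb their standard errors (>= 0).
#' @return Standard deviation of the ratio.
#' @examples
#' ratio_sd_delta(2, 4, 0.2, 0.4)  # ~0.0707
#' @export
ratio_sd_delta <- function(a, b, sa, sb) {
  stopifnot(sa >= 0, sb >= 0, b > 0)
  r <- a / b
  if (a == 0) {
    if (sa == 0) return(0)
    return(sa / b)  # limit of the delta formula as a -> 0
  }
  abs(r) * sqrt((sa / a)^2 + (sb / b)^2)
}

#' Uncertainty intervals for the mobilization report
#'
#' Propagates replicate-level uncertainty through the ratio calculus, either
#' by the first-order delta method on the supplied SEMs or by a seeded
#' nonparametric bootstrap over per-replicate frequencies.
#'
#' Delta method: each reported ratio r = a/b receives
#' sd = r sqrt((sa/a)^2 + (sb/b)^2) and a +/- 1.96 sd interval (floored at 0).
#' Bootstrap: replicate frequencies are resampled with replacement within each
#' mating, all report quantities recomputed, and 2.5%/97.5% percentile
#' intervals returned.
#'
#' @param freqs a [mating_frequency_set()]; for the bootstrap every mating
#'   used must carry `per_replicate` values.
#' @param method `"delta"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed integer seed for the bootstrap.
#' @return A data.frame with columns `quantity`, `estimate`, `sd`, `lower`,
#'   `upper`.
#' @export
propagate_uncertainty <- function(freqs, method = c("delta", "bootstrap"),
                                  n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(freqs, "mating_frequency_set"))
  point <- framework_quantities(freqs)
  if (method == "delta") {
    sem0 <- function(role) {
      s <- freqs[[role]]$sem
      if (is.na(s)) 0 else s
    }
    m <- function(role) freqs[[role]]$mean
    sds <- c(
      permissiveness_equivalents =
        unname(ratio_sd_delta(m("conj_comm"), m("conj_intra"),
                              sem0("conj_comm"), sem0("conj_intra"))),
      p_retro =
        unname(ratio_sd_delta(m("retro_intra"), m("conj_intra"),
                              sem0("retro_intra"), sem0("conj_intra"))),
      m_max = unname({
        # m_max = f_retro_comm * f_conj_intra / f_retro_intra: one ratio step
        # on f_retro_comm / p_retro with the p_retro sd from above
        p <- m("retro_intra") / m("conj_intra")
        ratio_sd_delta(m("retro_comm"), p, sem0("retro_comm"),
                       ratio_sd_delta(m("retro_intra"), m("conj_intra"),
                                      sem0("retro_intra"), sem0("conj_intra")))
      }),
      mobilization_equivalents = unname({
        mm <- point["m_max"]
        sd_mm <- ratio_sd_delta(m("retro_comm"),
                                m("retro_intra") / m("conj_intra"),
                                sem0("retro_comm"),
                                ratio_sd_delta(m("retro_intra"), m("conj_intra"),
                                               sem0("retro_intra"), sem0("conj_intra")))
        ratio_sd_delta(mm, m("conj_comm"), sd_mm, sem0("conj_comm"))
      })
    )
    out <- data.frame(quantity = names(point),
                      estimate = as.numeric(point),
                      sd = as.numeric(sds[names(point)]),
                      row.names = NULL)
    out$lower <- pmax(0, out$estimate - 1.96 * out$sd)
    out$upper <- out$estimate + 1.96 * out$sd
    return(out)
  }
  # bootstrap
  if (n_boot < 100) stop("n_boot must be at least 100")
  used <- c("conj_comm", "conj_intra", "retro_comm", "retro_intra")
  reps <- lapply(used, function(role) freqs[[role]]$per_replicate)
  names(reps) <- used
  if (any(vapply(reps, is.null, logical(1))))
    stop("bootstrap requires per-replicate frequencies for every mating used")
  set.seed(seed)
  draws <- replicate(n_boot, {
    means <- vapply(reps, function(x) mean(sample(x, replace = TRUE)),
                    numeric(1))
    if (means["conj_intra"] <= 0 || means["retro_intra"] <= 0 ||
        means["conj_comm"] <= 0)
      return(rep(NA_real_, 4))
    fs <- mating_frequency_set(conj_comm = means["conj_comm"],
                               conj_intra = means["conj_intra"],
                               retro_comm = means["retro_comm"],
                               retro_intra = means["retro_intra"])
    framework_quantities(fs)
  })
  est <- framework_quantities(freqs)
  data.frame(
    quantity = names(est),
    estimate = as.numeric(est),
    sd = apply(draws, 1, stats::sd, na.rm = TRUE),
    lower = apply(draws, 1, stats::quantile, probs = 0.025, na.rm = TRUE,
                  names = FALSE),
    upper = apply(draws, 1, stats::quantile, probs = 0.975, na.rm = TRUE,
                  names = FALSE),
    row.names = NULL
  )
}

framework_quantities <- function(freqs) {
  p_eq <- permissiveness_equivalents(freq_of(freqs, "conj_comm"),
                                     freq_of(freqs, "conj_intra"))
  p_retro <- suppressWarnings(
    retromobilization_probability(freq_of(freqs, "retro_intra"),
                                  freq_of(freqs, "conj_intra")))
  m_max <- maximal_mobilization_potential(freq_of(freqs, "retro_comm"), p_retro)
  m_eq <- mobilization_equivalents(m_max, freq_of(freqs, "conj_comm"))
  c(permissiveness_equivalents = unname(p_eq), p_retro = unname(p_retro),
    m_max = unname(m_max), mobilization_equivalents = unname(m_eq))
}

#' Build the full mobilization report
#'
#' Composes the calculus: permissiveness equivalents, retromobilization
#' probability, maximal mobilization potential (absolute and in
#' permissiveness equivalents), and the direct-mobilization fold changes.
#' Quantities whose inputs are missing are reported as `NA` and listed in
#' `$missing`; an all-missing input set is an error. All intermediate values
#' are carried at full precision; rounding happens only in the print method.
#'
#' @param freqs a [mating_frequency_set()].
#' @param uncertainty `"none"`, `"delta"` or `"bootstrap"`.
#' @param n_boot,seed bootstrap controls, see [propagate_uncertainty()].
#' @return An object of class `mobilization_report`.
#' @examples
#' freqs <- mating_frequency_set(conj_comm = 1.16e-4, conj_intra = 1.76e-3,
#'                               retro_comm = 1.16e-5, retro_intra = 8.34e-4,
#'                               direct_comm = 3.14e-3)
#' build_report(freqs)
#' @export
build_report <- function(freqs, uncertainty = c("none", "delta", "bootstrap"),
                         n_boot = 1000, seed = 1) {
  uncertainty <- match.arg(uncertainty)
  stopifnot(inherits(freqs, "mating_frequency_set"))
  means <- vapply(freqs, `[[`, numeric(1), "mean")
  if (all(is.na(means))) stop("all mating frequencies are missing")
  have <- function(...) all(!is.na(means[c(...)]))
  missing_q <- character(0)

  p_eq <- p_retro <- m_max <- m_eq <- NA_real_
  p_retro_warn <- FALSE
  if (have("conj_comm", "conj_intra"))
    p_eq <- permissiveness_equivalents(means["conj_comm"], means["conj_intra"])
  else missing_q <- c(missing_q, "permissiveness_equivalents")
  if (have("retro_intra", "conj_intra")) {
    p_retro <- withCallingHandlers(
      retromobilization_probability(means["retro_intra"], means["conj_intra"]),
      warning = function(w) {
        p_retro_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
  } else missing_q <- c(missing_q, "p_retro")
  if (!is.na(p_retro) && p_retro > 0 && have("retro_comm"))
    m_max <- maximal_mobilization_potential(means["retro_comm"], p_retro)
  else missing_q <- c(missing_q, "m_max")
  if (!is.na(m_max) && have("conj_comm"))
    m_eq <- mobilization_equivalents(m_max, means["conj_comm"])
  else missing_q <- c(missing_q, "mobilization_equivalents")

  folds <- list(direct_vs_retro = NA_real_, direct_vs_permissiveness = NA_real_)
  if (have("direct_comm", "retro_comm", "conj_comm") &&
      means["retro_comm"] > 0 && means["conj_comm"] > 0)
    folds <- fold_changes(freqs)
  else missing_q <- c(missing_q, "fold_changes")

  intervals <- if (uncertainty != "none")
    propagate_uncertainty(freqs, method = uncertainty, n_boot = n_boot,
                          seed = seed)
  else NULL

  structure(list(
    frequencies = freqs,
    permissiveness_equivalents = unname(p_eq),
    p_retro = unname(p_retro),
    p_retro_exceeds_one = p_retro_warn,
    m_max = unname(m_max),
    mobilization_equivalents = unname(m_eq),
    direct_vs_retro_fold = unname(folds$direct_vs_retro),
    direct_vs_permissiveness_fold = unname(folds$direct_vs_permissiveness),
    missing = missing_q,
    intervals = intervals
  ), class = "mobilization_report")
}

#' @export
print.mobilization_report <- function(x, ...) {
  cat("Community mobilization-potential report\n")
  fmt <- function(v, how) {
    if (is.na(v)) return("not available")
    switch(how,
           eq = sprintf("%.3f", v),
           pct = sprintf("%.1f%%", 100 * v),
           freq = format(signif(v, 3), scientific = TRUE),
           fold = sprintf("%.1f-fold", v))
  }
  cat("  permissiveness (intrastrain equivalents): ",
      fmt(x$permissiveness_equivalents, "eq"), "\n", sep = "")
  cat("  retromobilization probability:            ",
      fmt(x$p_retro, "pct"),
      if (isTRUE(x$p_retro_exceeds_one)) "  [exceeds 1: assay anomaly]" else "",
      "\n", sep = "")
  cat("  maximal mobilization potential:           ",
      fmt(x$m_max, "freq"), " T/R\n", sep = "")
  cat("  ... in permissiveness equivalents:        ",
      fmt(x$mobilization_equivalents, "eq"), "\n", sep = "")
  cat("  direct mobilization vs retromobilization: ",
      fmt(x$direct_vs_retro_fold, "fold"), "\n", sep = "")
  cat("  direct mobilization vs permissiveness:    ",
      fmt(x$direct_vs_permissiveness_fold, "fold"), "\n", sep = "")
  if (length(x$missing))
    cat("  missing inputs for:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a mobilization report to a data.frame
#'
#' @param x a `mobilization_report`.
#' @param ... unused.
#' @return data.frame with `quantity` and `value` columns (full precision).
#' @export
as.data.frame.mobilization_report <- function(x, ...) {
  data.frame(
    quantity = c("permissiveness_equivalents", "p_retro", "m_max",
                 "mobilization_equivalents", "direct_vs_retro_fold",
                 "direct_vs_permissiveness_fold"),
    value = c(x$permissiveness_equivalents, x$p_retro, x$m_max,
              x$mobilization_equivalents, x$direct_vs_retro_fold,
              x$direct_vs_permissiveness_fold)
  )
}
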