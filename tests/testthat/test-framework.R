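# The mobilization-potential calculus and its uncertainty propagation.

test_that("ratio operations reproduce the published worked values", {
  expect_equal(round(permissiveness_equivalents(1.16e-4, 1.76e-3), 3), 0.066)
  expect_equal(round(100 * retromobilization_probability(8.34e-4, 1.76e-3), 1),
               47.4)
  p <- retromobilization_probability(8.34e-4, 1.76e-3)
  expect_equal(signif(maximal_mobilization_potential(1.16e-5, p), 3), 2.45e-5)
  m <- maximal_mobilization_potential(1.16e-5, p)
  expect_equal(round(mobilization_equivalents(m, 1.16e-4), 3), 0.211)
})

test_that("ratio operations satisfy identity, zero and error contracts", {
  expect_equal(permissiveness_equivalents(3e-4, 3e-4), 1)
  expect_equal(permissiveness_equivalents(0, 5e-4), 0)
  expect_error(permissiveness_equivalents(1e-4, 0), "positive")
  expect_equal(retromobilization_probability(2e-3, 2e-3), 1)
  expect_equal(retromobilization_probability(0, 1e-3), 0)
  expect_error(retromobilization_probability(1e-3, 0), "positive")
  expect_warning(p <- retromobilization_probability(2e-3, 1e-3), "exceeds 1")
  expect_equal(p, 2)  # unclamped
  expect_equal(maximal_mobilization_potential(3e-5, 1), 3e-5)
  expect_equal(maximal_mobilization_potential(0, 0.4), 0)
  expect_error(maximal_mobilization_potential(1e-5, 0), "positive")
  expect_equal(mobilization_equivalents(2e-4, 2e-4), 1)
  expect_equal(mobilization_equivalents(0, 1e-4), 0)
})

test_that("fold changes are computed from the printed frequencies, not the prose", {
  fc <- fold_changes(published_frequencies())
  expect_equal(round(fc$direct_vs_retro, 1), 270.7)
  expect_equal(round(fc$direct_vs_permissiveness, 1), 27.1)
  eq <- mating_frequency_set(conj_comm = 1e-4, retro_comm = 1e-4,
                             retro_intra = 1e-4, conj_intra = 1e-4,
                             direct_comm = 1e-4)
  expect_equal(fold_changes(eq)$direct_vs_retro, 1)
  dbl <- mating_frequency_set(conj_comm = 1e-4, retro_comm = 1e-4,
                              retro_intra = 1e-4, conj_intra = 1e-4,
                              direct_comm = 2e-4)
  expect_equal(fold_changes(dbl)$direct_vs_retro, 2 * fold_changes(eq)$direct_vs_retro)
})

test_that("the composed potential equals the direct four-frequency formula", {
  set.seed(42)
  for (i in 1:200) {
    f <- 10^runif(4, -6, -2)  # conj_comm, conj_intra, retro_comm, retro_intra
    p <- suppressWarnings(retromobilization_probability(f[4], f[2]))
    lhs <- mobilization_equivalents(
      maximal_mobilization_potential(f[3], p), f[1])
    rhs <- (f[3] * f[2]) / (f[4] * f[1])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("report quantities are scale-invariant except m_max, which scales linearly", {
  f <- published_frequencies()
  r1 <- build_report(f)
  k <- 3.7
  f2 <- mating_frequency_set(conj_comm = k * 1.16e-4, conj_intra = k * 1.76e-3,
                             retro_comm = k * 1.16e-5, retro_intra = k * 8.34e-4,
                             direct_comm = k * 3.14e-3)
  r2 <- build_report(f2)
  expect_equal(r2$permissiveness_equivalents, r1$permissiveness_equivalents)
  expect_equal(r2$p_retro, r1$p_retro)
  expect_equal(r2$mobilization_equivalents, r1$mobilization_equivalents)
  expect_equal(r2$direct_vs_retro_fold, r1$direct_vs_retro_fold)
  expect_equal(r2$m_max, k * r1$m_max)
})

test_that("delta method matches the hand-computed ratio sd and zero SEMs give zero width", {
  expect_equal(ratio_sd_delta(2, 4, 0.2, 0.4), 0.5 * sqrt(0.01 + 0.01))
  expect_equal(round(ratio_sd_delta(2, 4, 0.2, 0.4), 4), 0.0707)

  freqs <- mating_frequency_set(
    conj_comm = list(mean = 1.16e-4, sem = 0),
    conj_intra = list(mean = 1.76e-3, sem = 0),
    retro_comm = list(mean = 1.16e-5, sem = 0),
    retro_intra = list(mean = 8.34e-4, sem = 0))
  iv <- propagate_uncertainty(freqs, method = "delta")
  expect_true(all(iv$sd == 0))
  expect_equal(iv$lower, iv$upper)
})

test_that("bootstrap intervals are reproducible and agree with the delta method", {
  # tight replicate sets (CV < 0.2) with enough replicates that the
  # resampled mean is not overly discrete
  set.seed(31)
  jitter9 <- function(base) base * (1 + runif(9, -0.15, 0.15))
  reps <- list(conj_comm = jitter9(1.16e-4),
               conj_intra = jitter9(1.76e-3),
               retro_comm = jitter9(1.16e-5),
               retro_intra = jitter9(8.34e-4))
  recs <- lapply(reps, function(x) {
    est <- aggregate_replicates(x)
    list(mean = est$mean, sem = est$sem, per_replicate = x)
  })
  freqs <- do.call(mating_frequency_set, recs)
  b1 <- propagate_uncertainty(freqs, "bootstrap", n_boot = 2000, seed = 99)
  b2 <- propagate_uncertainty(freqs, "bootstrap", n_boot = 2000, seed = 99)
  expect_identical(b1, b2)
  dl <- propagate_uncertainty(freqs, "delta")
  # compare interval widths per quantity within 20% relative width
  # (normalized by the estimate to put quantities on one scale)
  for (q in dl$quantity) {
    wd <- with(dl[dl$quantity == q, ], (upper - lower) / estimate)
    wb <- with(b1[b1$quantity == q, ], (upper - lower) / estimate)
    expect_lt(abs(wd - wb), 0.2 * max(wd, wb))
  }
  no_reps <- published_frequencies()
  expect_error(propagate_uncertainty(no_reps, "bootstrap"), "per-replicate")
  expect_error(propagate_uncertainty(freqs, "bootstrap", n_boot = 10),
               "at least 100")
})

test_that("build_report composes the calculus and tolerates missing inputs", {
  r <- build_report(published_frequencies())
  expect_s3_class(r, "mobilization_report")
  expect_equal(round(r$permissiveness_equivalents, 3), 0.066)
  expect_equal(round(100 * r$p_retro, 1), 47.4)
  expect_equal(signif(r$m_max, 3), 2.45e-5)
  expect_equal(round(r$mobilization_equivalents, 3), 0.211)
  expect_false(r$p_retro_exceeds_one)

  partial <- mating_frequency_set(conj_comm = 1.16e-4, conj_intra = 1.76e-3,
                                  retro_comm = 1.16e-5, retro_intra = 8.34e-4)
  rp <- build_report(partial)
  expect_true(is.na(rp$direct_vs_retro_fold))
  expect_true("fold_changes" %in% rp$missing)
  expect_equal(round(rp$mobilization_equivalents, 3), 0.211)

  degenerate <- mating_frequency_set(conj_comm = 1e-4, conj_intra = 1e-4,
                                     retro_comm = 1e-4, retro_intra = 1e-4,
                                     direct_comm = 1e-4)
  rd <- build_report(degenerate)
  expect_equal(rd$permissiveness_equivalents, 1)
  expect_equal(rd$p_retro, 1)
  expect_equal(rd$mobilization_equivalents, 1)

  expect_error(build_report(mating_frequency_set()), "missing")
})
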