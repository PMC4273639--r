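# Stochastic mating simulator: closed-form checks and parameter recovery.

test_that("conjugation counts follow the binomial closed form", {
  expect_equal(simulate_conjugation(
    sim_params(1000, p_conj = 0, seed = 1))$n_conjugation_events, 0)
  all_in <- simulate_conjugation(
    sim_params(500, permissive_fraction = 1, p_conj = 1, seed = 2))
  expect_equal(all_in$n_conjugation_events, 500)
  expect_equal(all_in$frequency, 1)

  n <- 1e5; p <- 1.76e-3
  out <- simulate_conjugation(sim_params(n, p_conj = p, seed = 11))
  expect_lt(abs(out$frequency - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("retromobilization is a two-step thinning of conjugal transfer", {
  none <- simulate_retromobilization(
    sim_params(1e4, p_conj = 0.5, p_mob_given_conj = 0, seed = 3))
  expect_equal(none$n_retro_events, 0)

  # retro events can never exceed step-1 successes, for any seed
  for (s in 1:20) {
    out <- simulate_retromobilization(
      sim_params(5000, mobilizer_fraction = 0.3, p_conj = 0.1,
                 p_mob_given_conj = 0.6, seed = s))
    expect_lte(out$n_retro_events, out$n_step1_successes)
  }

  # expected retro frequency is the product of the step probabilities
  n <- 1e6; p1 <- 1.76e-3; p2 <- 0.474
  out <- simulate_retromobilization(
    sim_params(n, mobilizer_fraction = 1, p_conj = p1,
               p_mob_given_conj = p2, seed = 17))
  pr <- p1 * p2
  expect_lt(abs(out$frequency - pr), 3 * sqrt(pr * (1 - pr) / n))

  expect_error(simulate_retromobilization(
    sim_params(10, p_conj = 0.1, donor_carries_mobilizer = TRUE, seed = 1)),
    "donor")
})

test_that("direct mobilization dominates retromobilization in expectation", {
  # closed forms: direct = permissive * p_conj * p_mob,
  #               retro  = mobilizer * p_conj * p_mob
  pf <- 0.4; mf <- 0.1; pc <- 0.05; pm <- 0.5
  expect_gt(pf * pc * pm, mf * pc * pm)
  n <- 2e5
  direct <- vapply(1:10, function(s) simulate_direct_mobilization(
    sim_params(n, permissive_fraction = pf, p_conj = pc,
               p_mob_given_conj = pm, donor_carries_mobilizer = TRUE,
               seed = s))$frequency, numeric(1))
  retro <- vapply(1:10, function(s) simulate_retromobilization(
    sim_params(n, mobilizer_fraction = mf, p_conj = pc,
               p_mob_given_conj = pm, seed = s + 100))$frequency, numeric(1))
  expect_gt(mean(direct), mean(retro))

  full <- simulate_direct_mobilization(
    sim_params(300, permissive_fraction = 1, p_conj = 1,
               p_mob_given_conj = 1, donor_carries_mobilizer = TRUE, seed = 5))
  expect_equal(full$n_direct_events, 300)
  expect_error(simulate_direct_mobilization(
    sim_params(10, p_conj = 0.1, seed = 1)), "donor_carries_mobilizer")
  expect_error(sim_params(10, p_conj = 1.2), "\\[0, 1\\]")
})

test_that("simulation outcomes are bit-identical under a fixed seed", {
  p <- sim_params(1e5, permissive_fraction = 0.3, mobilizer_fraction = 0.2,
                  p_conj = 0.01, p_mob_given_conj = 0.5, seed = 123)
  expect_identical(simulate_conjugation(p), simulate_conjugation(p))
  expect_identical(simulate_retromobilization(p), simulate_retromobilization(p))
  f1 <- simulate_mating_panel(1e5, 0.1, 0.05, 0.01, 0.5, seed = 7)
  f2 <- simulate_mating_panel(1e5, 0.1, 0.05, 0.01, 0.5, seed = 7)
  expect_equal(f1, f2, ignore_attr = TRUE)
})

test_that("the calculus recovers simulator parameters", {
  # deterministic limit: probabilities 0/1 give exact recovery
  exact <- recover_parameters(1000, permissive_fraction = 1,
                              mobilizer_fraction = 1, p_conj = 1,
                              p_mob_given_conj = 1, seed = 2)
  expect_false(exact$skipped)
  expect_equal(exact$report$p_retro, 1)
  expect_equal(exact$report$permissiveness_equivalents, 1)

  # stochastic recovery: median recovered p_retro near the truth
  meds <- vapply(1:20, function(s)
    recover_parameters(1e6, permissive_fraction = 0.1,
                       mobilizer_fraction = 0.05, p_conj = 2e-3,
                       p_mob_given_conj = 0.5, seed = s)$report$p_retro,
    numeric(1))
  expect_gt(median(meds), 0.45)
  expect_lt(median(meds), 0.55)

  # recovered permissiveness equivalents concentrate near permissive_fraction
  peq <- vapply(1:20, function(s)
    recover_parameters(1e6, permissive_fraction = 0.2,
                       mobilizer_fraction = 0.05, p_conj = 2e-3,
                       p_mob_given_conj = 0.5, seed = s + 40)$report$permissiveness_equivalents,
    numeric(1))
  expect_gt(median(peq), 0.15)
  expect_lt(median(peq), 0.25)

  # a zero realized divisor flags the seed and skips recovery
  sk <- recover_parameters(10, permissive_fraction = 0.01,
                           mobilizer_fraction = 0.01, p_conj = 1e-4,
                           p_mob_given_conj = 0.5, seed = 3)
  expect_true(sk$skipped)
  expect_null(sk$report)
})
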