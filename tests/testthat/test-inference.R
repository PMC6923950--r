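test_that("log prior is the standard normal in log space", {
  expect_equal(log_prior(rep(0, 9)), -(9 / 2) * log(2 * pi))
  th <- rnorm(9)
  expect_equal(log_prior(th), log_prior(-th))
  expect_equal(log_prior(c(th, 0)) - log_prior(th), -0.5 * log(2 * pi))
})

test_that("log likelihood equals the closed form at a perfect fit", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  times <- seq(0, 88, 0.25)
  traj <- simulate_microenv(pv$params, pv$init, times, "H2")
  m <- total_mass(traj)
  fr <- steady_fractions(traj, 80)
  v <- rep(2e-4, length(times))
  data <- growth_dataset(times, m, v, 6, fr[["frac_e"]], fr[["frac_q"]],
                         sigma_alpha_e = 0.02, sigma_alpha_q = 0.02,
                         t_N = 80)
  ll <- log_likelihood(data, default_truth_theta(), "H2")
  ll_expected <- -0.5 * sum(log(2 * pi * v)) - 0.5 * log(2 * pi * 0.02^2) -
    0.5 * log(2 * pi * 0.02^2)
  expect_equal(ll, ll_expected, tolerance = 1e-6)

  # doubling the variances at a perfect fit lowers log L by N/2 * log 2
  data2 <- data
  data2$var_mass <- 2 * v
  expect_equal(log_likelihood(data2, default_truth_theta(), "H2") - ll,
               -0.5 * length(v) * log(2), tolerance = 1e-6)

  # composition-only dataset: exactly the two composition terms
  data0 <- growth_dataset(numeric(0), numeric(0), numeric(0), 6,
                          fr[["frac_e"]], fr[["frac_q"]], t_N = 80)
  expect_equal(log_likelihood(data0, default_truth_theta(), "H2"),
               -log(2 * pi * 0.02^2), tolerance = 1e-6)

  # an unintegrable corner scores the failure sentinel, not an error
  bad <- rep(20, 9)
  expect_equal(log_likelihood(data, bad, "H2"), -1e10)
})

test_that("temperature ladder follows the fifth-power schedule", {
  lad <- make_ladder(30)
  expect_equal(lad[1], 0)
  expect_equal(lad[30], 1)
  expect_equal(lad[2], (1 / 29)^5)
  expect_true(all(diff(lad) > 0))
  expect_error(make_ladder(1), "at least 2")
})

test_that("the prior chain reproduces the prior and runs are seeded", {
  toy <- conjugate_toy(n = 10, seed = 4)
  cfg <- mcmc_config(n_burn = 2000, adapt_window = 1000, thin = 2,
                     n_keep = 5000)
  cs <- pt_sample(toy$loglik, log_prior, 1, make_ladder(5), cfg, seed = 11)
  x0 <- cs$samples[, 1, 1]
  expect_lt(abs(mean(x0)), 4 / sqrt(length(x0)) * 3)
  expect_equal(var(x0), 1, tolerance = 0.1)

  cs2 <- pt_sample(toy$loglik, log_prior, 1, make_ladder(5), cfg, seed = 11)
  expect_identical(cs$samples, cs2$samples)
})

test_that("the cold chain matches the conjugate posterior", {
  toy <- conjugate_toy(n = 10, seed = 4)
  cfg <- mcmc_config(n_burn = 2000, adapt_window = 1000, thin = 2,
                     n_keep = 4000)
  cs <- pt_sample(toy$loglik, log_prior, 1, make_ladder(5), cfg, seed = 2)
  x <- cs$samples[, 1, 5]
  se_mean <- sqrt(toy$post_var / length(x)) * 3  # crude autocorr inflation
  expect_lt(abs(mean(x) - toy$post_mean), 3 * se_mean)
  expect_equal(var(x), toy$post_var, tolerance = 0.15)
})

test_that("swap moves preserve the marginals on a two-temperature toy", {
  # theta ~ N(0,1) prior, one observation; with beta = (0, 1) the two
  # chains target the prior and the exact conjugate posterior
  toy <- conjugate_toy(n = 1, seed = 9)
  cfg <- mcmc_config(n_burn = 1000, adapt_window = 500, thin = 2,
                     n_keep = 4000)
  cs <- pt_sample(toy$loglik, log_prior, 1, make_ladder(2), cfg, seed = 3)
  expect_gt(cs$swap_accept, 0.2)  # swaps do happen
  expect_equal(var(cs$samples[, 1, 1]), 1, tolerance = 0.12)
  expect_equal(mean(cs$samples[, 1, 2]), toy$post_mean, tolerance = 0.05)
  expect_equal(var(cs$samples[, 1, 2]), toy$post_var, tolerance = 0.15)
})

test_that("thermodynamic integration is exact for flat likelihoods and
           improves with ladder refinement", {
  # identically-1 likelihood: evidence must be exactly 0
  cfg <- mcmc_config(n_burn = 200, adapt_window = 100, thin = 1,
                     n_keep = 200)
  cs <- pt_sample(function(th) 0, log_prior, 1, make_ladder(5), cfg,
                  seed = 1)
  expect_equal(thermodynamic_evidence(cs)$log_evidence, 0)

  # quadrature error shrinks on average as the ladder is refined
  toy <- conjugate_toy(n = 10, seed = 21)
  cfg2 <- mcmc_config(n_burn = 500, adapt_window = 300, thin = 1,
                      n_keep = 1500)
  err <- function(nb, seed) {
    cs <- pt_sample(toy$loglik, log_prior, 1, make_ladder(nb), cfg2,
                    seed = seed)
    thermodynamic_evidence(cs)$log_evidence - toy$log_evidence
  }
  e10 <- vapply(1:8, function(s) err(10, s), 0)
  e30 <- vapply(1:8, function(s) err(30, 100 + s), 0)
  expect_lt(mean(abs(e30)), mean(abs(e10)))
})

test_that("hypothesis posterior normalises evidence correctly", {
  expect_equal(unname(hypothesis_posterior(c(0, 0, 0))), rep(1 / 3, 3))
  expect_equal(unname(hypothesis_posterior(c(0, -log(9)))), c(0.9, 0.1))
  p <- hypothesis_posterior(c(0, -Inf, 0))
  expect_equal(unname(p), c(0.5, 0, 0.5))
  expect_equal(sum(hypothesis_posterior(c(-1000, -1010, -990))), 1)
  expect_equal(unname(hypothesis_posterior(c(0, 0), c(0.8, 0.2))),
               c(0.8, 0.2))
  expect_error(hypothesis_posterior(c(-Inf, -Inf)), "-Inf")
})

test_that("PSRF detects agreement, disagreement, and is affine invariant", {
  set.seed(12)
  base <- matrix(rnorm(500 * 2), 500, 2)
  # identical chains: R equals 1 up to the (n-1)/n factor
  r_same <- psrf(list(base, base, base))
  expect_equal(unname(r_same), rep(sqrt(499 / 500), 2), tolerance = 1e-12)
  # disjoint chains: R far above 1
  r_far <- psrf(list(base, base + 50))
  expect_true(all(r_far > 10))
  # common affine transformation leaves R unchanged
  chains <- list(matrix(rnorm(400), 200, 2), matrix(rnorm(400), 200, 2))
  tr <- lapply(chains, function(ch) sweep(ch * 3.7, 2, c(5, -2), "+"))
  expect_equal(psrf(chains), psrf(tr), tolerance = 1e-10)
  expect_error(psrf(list(base)), "at least two")
})

test_that("multistart initialization finds the prior mode at beta = 0
           and attaches valid proposal covariances", {
  gd <- generate_growth_curves(seed = 3)
  lad <- make_ladder(3)
  init <- init_by_multistart(gd, "H2", lad, n_starts = 2, seed = 2)
  expect_equal(dim(init), c(9, 3))
  # beta = 0 column: the prior mode (origin)
  expect_lt(max(abs(init[, 1])), 0.05)
  # the posterior-level start fits the data at least as well as a
  # generic neighbourhood of the truth
  ll_init <- log_likelihood(gd, init[, 3], "H2")
  ll_truth <- log_likelihood(gd, default_truth_theta(), "H2")
  expect_gt(ll_init, ll_truth - 50)
  # attached Laplace proposal covariances are valid SPD matrices
  pc <- attr(init, "prop_cov")
  expect_length(pc, 3)
  expect_true(all(vapply(pc, function(S)
    min(eigen(S, symmetric = TRUE)$values) > 0, TRUE)))
})

test_that("local refinement from the truth stays at the truth on
           near-noiseless data", {
  pv <- params_from_vector(default_truth_theta(), "H2")
  times <- seq(0, 88, 0.25)
  traj <- simulate_microenv(pv$params, pv$init, times, "H2")
  fr <- steady_fractions(traj, 80)
  gd <- growth_dataset(times, total_mass(traj), rep(1e-4, length(times)), 6,
                       fr[["frac_e"]], fr[["frac_q"]], t_N = 80)
  ref <- yeastcolony:::.refine_map(default_truth_theta(), gd, "H2")
  expect_lt(max(abs(ref$theta - default_truth_theta())), 0.05)
})

test_that("MAP refinement never falls below the best sampled point", {
  toy <- conjugate_toy(n = 6, seed = 8)
  gd <- generate_growth_curves(seed = 44)
  cfg <- mcmc_config(n_burn = 300, adapt_window = 200, thin = 2,
                     n_keep = 100)
  init <- init_by_multistart(gd, "H2", make_ladder(4), n_starts = 1,
                             seed = 1)
  cs <- run_population_mcmc(gd, "H2", make_ladder(4), cfg, init = init,
                            seed = 6)
  m <- map_estimate(cs, gd, "H2")
  nb <- dim(cs$samples)[3]
  best_sampled <- max(cs$loglik[, nb] +
                        apply(cs$samples[, , nb], 1, log_prior))
  expect_gte(m$log_posterior, best_sampled)
  # deterministic given the chains
  expect_identical(map_estimate(cs, gd, "H2"), m)
})
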