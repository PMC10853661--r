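test_that("membership sampling: diagnostic, symmetric and degenerate cases", {
  # population-unique alleles: deterministic assignment
  logL <- rbind(c(0, -Inf), c(-Inf, 0), c(0, -Inf))
  set.seed(1)
  expect_equal(sample_memberships(logL, c(0.5, 0.5)), c(1L, 2L, 1L))

  # identical likelihoods: assignment probabilities equal p
  set.seed(2)
  z <- replicate(4000, sample_memberships(matrix(0, 2, 2), c(0.8, 0.2)))
  expect_equal(mean(z == 1), 0.8, tolerance = 0.03)

  # one-hot p: everyone goes there
  set.seed(3)
  expect_equal(sample_memberships(matrix(0, 3, 2), c(1, 0)), rep(1L, 3))

  # unassignable fish is an error naming the individual
  bad <- matrix(-Inf, 1, 2, dimnames = list("fishX", NULL))
  expect_error(sample_memberships(bad, c(0.5, 0.5)), "fishX")
})

test_that("proportion draws match closed-form Dirichlet moments", {
  # posterior mean of p1 with counts (3,1), alpha (0.5,0.5) is 3.5/5
  set.seed(4)
  draws <- replicate(50000, sample_proportions(c(3, 1), c(0.5, 0.5))[1])
  expect_lt(abs(mean(draws) - 0.7), 0.005)
  expect_lt(abs(stats::var(draws) - 0.7 * 0.3 / 6), 0.005)

  # zero counts: prior draw
  set.seed(5)
  prior <- replicate(50000, sample_proportions(c(0, 0), c(2, 1))[1])
  expect_lt(abs(mean(prior) - 2 / 3), 0.005)
})

test_that("allele-frequency draws concentrate on conditioning counts", {
  # no data: prior Dirichlet(beta)
  base0 <- make_baseline("P1", list(loc("L1")), list(matrix(c(0L, 0L), 1)))
  set.seed(6)
  pri <- replicate(20000, sample_allele_freqs(base0)[[1]][1, 1])
  expect_equal(mean(pri), 0.5, tolerance = 0.01)

  # huge baseline counts: draws concentrate at the empirical frequencies
  baseN <- make_baseline("P1", list(loc("L1")),
                         list(matrix(c(60000L, 20000L), 1)))
  set.seed(7)
  conc <- replicate(200, sample_allele_freqs(baseN)[[1]][1, 1])
  expect_equal(mean(conc), 0.75, tolerance = 0.005)
  expect_true(all(abs(conc - 0.75) < 0.01))

  # frequencies sum to one per locus and assigned fish add their counts
  mix <- make_mixture(c("f1", "f2"), list(loc("L1")),
                      list(rbind(c(2L, 0L), c(0L, 2L))))
  q <- sample_allele_freqs(baseN, mix, z = c(1L, 1L))
  expect_equal(unname(rowSums(q[[1]])), 1)
})

test_that("single-baseline run: K = 1 and label-permutation equivariance", {
  base1 <- make_baseline("P1", list(loc("L1")), list(matrix(c(6L, 2L), 1)))
  mix <- make_mixture(c("f1", "f2"), list(loc("L1")),
                      list(rbind(c(2L, 0L), c(1L, 1L))))
  fit <- run_single_gsi(mix, base1, c(P1 = "G1"), mcmc = quick_mcmc(1))
  expect_true(all(fit$combined[[1]] == 1))

  # permuting population labels leaves group-level posterior means
  # unchanged (up to Monte-Carlo seed-path differences)
  base2 <- make_baseline(c("P1", "P2"), list(loc("L1")),
                         list(rbind(c(7, 1), c(2, 6))))
  base2r <- make_baseline(c("P2", "P1"), list(loc("L1")),
                          list(rbind(c(2, 6), c(7, 1))))
  g <- c(P1 = "G1", P2 = "G2")
  mcp <- quick_mcmc(9, n_chains = 3, n_iter = 3000, n_burn = 500)
  f1 <- run_single_gsi(mix, base2, g, mcmc = mcp)
  f2 <- run_single_gsi(mix, base2r, g, mcmc = mcp)
  tol <- pmax(3 * (mc_se(f1) + mc_se(f2)), 0.01)
  expect_true(all(abs(posterior_means(f1)[c("G1", "G2")] -
                        posterior_means(f2)[c("G1", "G2")]) < tol))
})

test_that("posterior means match the exact enumeration oracle (single baseline)", {
  set.seed(11)
  for (seed in c(101, 202, 303)) {
    inst <- rand_tiny_instance(seed, M = 2)
    groups <- c(P1 = "A", P2 = "B")
    fit <- run_single_gsi(inst$mix_broad, inst$broad_base, groups,
                          mcmc = mcmc_config(n_chains = 4, n_iter = 2000,
                                             n_burn = 500, thin = 1,
                                             seed = seed + 1))
    est <- posterior_means(fit)
    ora <- oracle_single_means(inst$mix_broad, inst$broad_base, groups)
    tol <- pmax(3 * mc_se(fit), 1e-3)
    expect_true(all(abs(est[names(ora)] - ora) < tol),
                info = paste("seed", seed))
  }
})

test_that("every retained draw is a simplex", {
  inst <- rand_tiny_instance(7, M = 3)
  fit <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                   inst$regional_bases, inst$rm, mcmc = quick_mcmc(2))
  for (ch in fit$combined) {
    expect_true(all(ch >= 0))
    expect_equal(unname(rowSums(ch)), rep(1, nrow(ch)), tolerance = 1e-12)
  }
  for (ch in fit$pop) {
    expect_equal(unname(rowSums(ch)), rep(1, nrow(ch)), tolerance = 1e-12)
  }
})

test_that("conditional and fully Bayesian models agree when the baseline is large", {
  sc <- synthetic_scenario(n_broad_loci = 15, n_regional_loci = 3,
                           pops_per_group = 2, regional_pops_per_group = 2,
                           nonregional_groups = c("X", "Y"),
                           regional_groups = list(r1 = "Z"),
                           true_group_proportions = c(0.5, 0.3, 0.2),
                           baseline_n = 400, mixture_size = 60)
  st <- simulate_study(sc, seed = 13)
  syn <- synthesize_mixture(st$broad, st$regional, st$region_map,
                            sc$true_group_proportions, 60, seed = 14)
  groups <- st$region_map$broad_group_of
  mc_c <- mcmc_config(n_chains = 3, n_iter = 1500, n_burn = 500, thin = 1,
                      seed = 15)
  mc_f <- mcmc_config(n_chains = 3, n_iter = 1500, n_burn = 500, thin = 1,
                      seed = 16, model = "fully_bayesian")
  fc <- run_single_gsi(syn$mix_broad, syn$broad_base, groups, mcmc = mc_c)
  ff <- run_single_gsi(syn$mix_broad, syn$broad_base, groups, mcmc = mc_f)
  mc_err <- pmax(3 * (mc_se(fc) + mc_se(ff)), 0.02)
  expect_true(all(abs(posterior_means(fc) - posterior_means(ff)) < mc_err))
})
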