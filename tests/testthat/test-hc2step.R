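test_that("assignment probabilities reflect membership draw frequencies", {
  inst <- diagnostic_instance()
  fit <- run_single_gsi(inst$mix_broad, inst$broad_base,
                        inst$rm$broad_group_of, mcmc = quick_mcmc(21))
  at <- assignment_probabilities(fit, inst$rm)
  expect_equal(unname(rowSums(at$probs)), rep(1, nrow(at$probs)))
  # diagnostic fish: region probability essentially 1 (or 0); the prior
  # mass beta leaves a sliver of cross-assignment even for fixed alleles
  expect_true(all(at$region_probs[inst$source != "P1", "r1"] >= 0.99))
  expect_true(all(at$region_probs[inst$source == "P1", "r1"] <= 0.01))
})

test_that("stage-2 selection uses a strict threshold", {
  at <- structure(list(
    probs = matrix(c(0.8, 0.81, 0.2, 0.19), 2,
                   dimnames = list(c("f1", "f2"), c("B", "A"))),
    region_probs = matrix(c(0.8, 0.81), 2,
                          dimnames = list(c("f1", "f2"), "r1")),
    total = 100
  ), class = "assignment_table")
  expect_equal(select_for_stage2(at, "r1", 0.8), 2L)   # 0.8 exactly: out
  expect_equal(select_for_stage2(at, "r1", 0), c(1L, 2L))
  expect_equal(select_for_stage2(at, "r1", 0.9), integer(0))
})

test_that("with diagnostic markers the two-step and multistage answers agree", {
  inst <- diagnostic_instance()
  mc <- mcmc_config(n_chains = 3, n_iter = 2000, n_burn = 500, thin = 1,
                    seed = 8)
  ms <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                  inst$regional_bases, inst$rm, mcmc = mc)
  hc <- run_hc2step(inst$mix_broad, inst$mix_regional, inst$broad_base,
                    inst$regional_bases, inst$rm, mcmc = mc, tau = 0)
  del <- abs(posterior_means(ms) - posterior_means(hc)[names(posterior_means(ms))])
  expect_true(all(del < pmax(3 * (mc_se(ms) + mc_se(hc)), 0.01)))
  # and both recover the constructed truth
  expect_equal(posterior_means(hc)[names(inst$truth)], inst$truth,
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("combined two-step means sum to one by construction", {
  inst <- rand_tiny_instance(55, M = 3)
  hc <- run_hc2step(inst$mix_broad, inst$mix_regional, inst$broad_base,
                    inst$regional_bases, inst$rm,
                    mcmc = quick_mcmc(12), tau = 0.5)
  expect_equal(sum(posterior_means(hc)), 1, tolerance = 1e-10)
  hc2 <- run_hc2step(inst$mix_broad, inst$mix_regional, inst$broad_base,
                     inst$regional_bases, inst$rm,
                     mcmc = quick_mcmc(12), tau = 0.5,
                     rescale = "selected_fraction")
  expect_equal(names(posterior_means(hc2)), c("A", "Ba", "Bb"))
})

test_that("an empty stage-2 selection warns and reports the prior", {
  inst <- diagnostic_instance()
  expect_warning(
    hc <- run_hc2step(inst$mix_broad, inst$mix_regional, inst$broad_base,
                      inst$regional_bases, inst$rm,
                      mcmc = quick_mcmc(13), tau = 1),
    "prior only"
  )
  pm <- posterior_means(hc)
  # prior over the two regional groups is symmetric
  expect_equal(unname(pm["Ba"] / (pm["Ba"] + pm["Bb"])), 0.5,
               tolerance = 0.05)
})
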