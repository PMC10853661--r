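test_that("regional eligibility follows the current broad assignment", {
  rm <- tiny_region_map()
  pops <- c("P1", "P2")
  e <- regional_eligibility(c(1L, 2L, 2L), rm, pops)
  expect_equal(unname(e[, "r1"]), c(FALSE, TRUE, TRUE))
  # fish assigned outside every region are eligible nowhere
  expect_equal(unname(rowSums(e)), c(0, 1, 1))
})

test_that("regional membership and proportion draws handle degenerate cases", {
  logL <- rbind(c(0, -Inf), c(-5, -5), c(-Inf, 0))
  # ineligible fish keep the zero (NA) membership
  set.seed(1)
  zr <- sample_regional_memberships(logL, c(0.5, 0.5),
                                    eligible = c(TRUE, FALSE, TRUE))
  expect_equal(is.na(zr), c(FALSE, TRUE, FALSE))
  expect_equal(zr[c(1, 3)], c(1L, 2L))

  # zero eligible fish: empty draw, proportions fall back to the prior
  zr0 <- sample_regional_memberships(logL, c(0.5, 0.5),
                                     eligible = rep(FALSE, 3))
  expect_true(all(is.na(zr0)))
  set.seed(2)
  pri <- replicate(20000, sample_regional_proportions(zr0, 2, c(2, 1))[1])
  expect_equal(mean(pri), 2 / 3, tolerance = 0.01)

  # counts (10, 0) with alpha (0.5, 0.5): mean 10.5/11
  set.seed(3)
  post <- replicate(20000,
                    sample_regional_proportions(rep(1L, 10), 2,
                                                c(0.5, 0.5))[1])
  expect_equal(mean(post), 10.5 / 11, tolerance = 0.01)
})

test_that("proportion combination follows the two-stage scaling rule", {
  rm <- region_map(c(p1 = "A", p2 = "B", p3 = "C"), c(C = "yuk"),
                   list(yuk = c(r1 = "Ca", r2 = "Cb")))
  out <- combine_proportions(c(A = 0.2, B = 0.3, C = 0.5),
                             list(yuk = c(Ca = 0.4, Cb = 0.6)), rm)
  expect_equal(out, c(A = 0.2, B = 0.3, Ca = 0.2, Cb = 0.3))
  expect_equal(sum(out), 1)

  # no regions: identity on broad group proportions
  rm0 <- region_map(c(p1 = "A", p2 = "B"))
  expect_equal(combine_proportions(c(A = 0.4, B = 0.6), list(), rm0),
               c(A = 0.4, B = 0.6))

  # sums to one for arbitrary simplex inputs
  set.seed(5)
  for (i in 1:20) {
    pb <- rdirichlet1(rep(1, 3)); names(pb) <- c("A", "B", "C")
    pr <- rdirichlet1(rep(1, 2)); names(pr) <- c("Ca", "Cb")
    expect_equal(sum(combine_proportions(pb, list(yuk = pr), rm)), 1)
  }
})

test_that("zero regions reduces bit-identically to the single-baseline sampler", {
  inst <- rand_tiny_instance(31, M = 3)
  groups <- c(P1 = "A", P2 = "B")
  rm0 <- region_map(broad_group_of = groups)
  mc <- quick_mcmc(77)
  f_single <- run_single_gsi(inst$mix_broad, inst$broad_base, groups,
                             mcmc = mc)
  f_ms <- run_msgsi(inst$mix_broad, list(), inst$broad_base, list(), rm0,
                    mcmc = mc)
  expect_identical(f_single$combined, f_ms$combined)
  expect_identical(f_single$pop, f_ms$pop)
})

test_that("multistage posterior means match the exact joint enumeration oracle", {
  for (seed in c(17, 29, 43, 57, 71)) {
    inst <- rand_tiny_instance(seed, M = 3)
    fit <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                     inst$regional_bases, inst$rm,
                     mcmc = mcmc_config(n_chains = 4, n_iter = 2000,
                                        n_burn = 500, thin = 1,
                                        seed = seed * 3 + 1))
    est <- posterior_means(fit)
    ora <- oracle_msgsi_means(inst$mix_broad, inst$mix_regional,
                              inst$broad_base, inst$regional_bases$r1,
                              inst$rm)
    tol <- pmax(3 * mc_se(fit), 1e-3)
    expect_true(all(abs(est[names(ora)] - ora) < tol),
                info = paste("instance seed", seed))
  }
})

test_that("doubly diagnostic fish are assigned to their true regional population", {
  inst <- diagnostic_instance()
  mc <- mcmc_config(n_chains = 2, n_iter = 1000, n_burn = 200, thin = 1,
                    seed = 5, record_memberships = TRUE)
  fit <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                   inst$regional_bases, inst$rm, mcmc = mc)
  # broad stage: all regional fish sit in P2 in >= 99% of retained draws
  hit_rate <- fit$z_hits[cbind(seq_along(inst$source),
                               ifelse(inst$source == "P1", 1L, 2L))] /
    sum(fit$z_hits[1, ])
  expect_true(all(hit_rate >= 0.99))
  # and the combined means recover the construction's proportions
  expect_equal(posterior_means(fit)[names(inst$truth)], inst$truth,
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("marginalization: regional groups sum to the region's broad total", {
  inst <- rand_tiny_instance(99, M = 3)
  fit <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                   inst$regional_bases, inst$rm,
                   mcmc = quick_mcmc(6, n_chains = 2, n_iter = 2000,
                                     n_burn = 500))
  for (ci in seq_along(fit$combined)) {
    reg_sum <- rowSums(fit$combined[[ci]][, c("Ba", "Bb")])
    broad_total <- fit$broad_group[[ci]][, "B"]
    expect_equal(reg_sum, broad_total, tolerance = 1e-12)
  }
})

test_that("a region without a matching baseline or mixture fails before sampling", {
  inst <- rand_tiny_instance(3, M = 2)
  expect_error(
    run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
              list(), inst$rm),
    "without a regional baseline"
  )
  expect_error(
    run_msgsi(inst$mix_broad, list(), inst$broad_base,
              inst$regional_bases, inst$rm),
    "without a regional mixture"
  )
})
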