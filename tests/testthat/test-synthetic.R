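test_that("table-style group sizes reproduce from proportions by largest remainder", {
  sizes <- largest_remainder(c(0.27, 0.10, 0.19, 0.13, 0.31), 205)
  expect_equal(sizes, c(55L, 20L, 39L, 27L, 64L))
  expect_equal(sum(sizes), 205L)
  expect_equal(round(55 / 205, 2), 0.27)
  # exhaustive sanity on random simplexes
  set.seed(4)
  for (i in 1:20) {
    p <- rdirichlet1(rep(1, sample(2:6, 1)))
    s <- largest_remainder(p, 117)
    expect_equal(sum(s), 117L)
    expect_true(all(abs(s - p * 117) < 1))
  }
})

test_that("differentiation is monotone in 1/theta (F_ST from latent frequencies)", {
  fst_at <- function(theta, seed) {
    sc <- synthetic_scenario(n_broad_loci = 200, n_regional_loci = 3,
                             pops_per_group = 1, regional_pops_per_group = 1,
                             nonregional_groups = c("X", "Y"),
                             regional_groups = list(r1 = "Z"),
                             true_group_proportions = c(0.4, 0.4, 0.2),
                             theta_broad = theta, baseline_n = 5)
    b <- generate_baseline(sc, "broad", seed = seed)
    # Wright-style F_ST per locus from the two latent frequency vectors
    fst <- vapply(b$q_true, function(q) {
      pbar <- colMeans(q[1:2, ])
      ht <- 1 - sum(pbar^2)
      hs <- 1 - mean(rowSums(q[1:2, ]^2))
      if (ht <= 0) 0 else (ht - hs) / ht
    }, numeric(1))
    mean(fst)
  }
  expect_gt(fst_at(0.1, 21), fst_at(10, 21))
  expect_gt(fst_at(0.1, 22), fst_at(10, 22))
})

test_that("generation is reproducible and baselines satisfy their invariants", {
  sc <- synthetic_scenario(n_broad_loci = 4, n_regional_loci = 5,
                           baseline_n = 8)
  b1 <- generate_baseline(sc, "broad", seed = 3)
  b2 <- generate_baseline(sc, "broad", seed = 3)
  expect_identical(b1$counts, b2$counts)
  expect_silent(validate_baseline(b1))
  r1 <- generate_baseline(sc, "Upriver", seed = 5)
  expect_silent(validate_baseline(r1))
  expect_equal(length(r1$populations), 16L)  # 4 groups x 4 pops
  expect_setequal(r1$aux_pops, paste0("Coastal_p", 1:5))
})

test_that("mixture synthesis: sizes, truth record, conservation, exhaustion", {
  sc <- synthetic_scenario(n_broad_loci = 3, n_regional_loci = 3,
                           baseline_n = 10, mixture_size = 20)
  st <- simulate_study(sc, seed = 9)
  syn <- synthesize_mixture(st$broad, st$regional, st$region_map,
                            sc$true_group_proportions, 20, seed = 1)
  expect_equal(sum(syn$truth$sizes), 20L)
  expect_equal(syn$truth$proportions,
               syn$truth$sizes / 20, ignore_attr = TRUE)
  # conservation: pruned baseline totals = original - mixture draws per pop
  drawn <- table(syn$truth$fish$pop)
  for (p in names(drawn)) {
    k <- match(p, st$broad$populations)
    expect_equal(st$broad$sample_sizes[k, 1] - as.integer(drawn[[p]]),
                 syn$broad_base$sample_sizes[k, 1])
  }
  expect_silent(validate_baseline(syn$broad_base))
  expect_silent(validate_baseline(syn$regional_bases$Upriver))
  expect_silent(validate_mixture(syn$mix_broad))

  # M = 1 goes to exactly one group, and the record says which
  one <- synthesize_mixture(st$broad, st$regional, st$region_map,
                            sc$true_group_proportions, 1, seed = 2)
  expect_equal(sum(one$truth$sizes), 1L)
  expect_equal(sum(one$truth$sizes > 0), 1L)
  expect_equal(unique(one$truth$fish$group),
               names(which(one$truth$sizes == 1)))

  # reproducibility
  syn2 <- synthesize_mixture(st$broad, st$regional, st$region_map,
                             sc$true_group_proportions, 20, seed = 1)
  expect_identical(syn$mix_broad, syn2$mix_broad)

  # requesting more fish than the baselines hold is an error
  too_many <- stats::setNames(c(1, 0, 0, 0, 0),
                              names(sc$true_group_proportions))
  expect_error(
    synthesize_mixture(st$broad, st$regional, st$region_map, too_many,
                       100, seed = 3),
    "exceed available"
  )
})

test_that("random truths are flat-Dirichlet distributed and reproducible", {
  p1 <- random_true_proportions(5, seed = 8)
  expect_identical(p1, random_true_proportions(5, seed = 8))
  expect_equal(sum(p1), 1)
  expect_equal(random_true_proportions(1, seed = 1), 1)
  set.seed(33)
  draws <- replicate(10000, random_true_proportions(4))
  expect_equal(rowMeans(draws), rep(0.25, 4), tolerance = 0.04)
  expect_true(all(abs(rowMeans(draws) - 0.25) < 0.01))
})
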