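test_that("Gelman-Rubin PSRF: exact toy value, copies, and disjoint chains", {
  # hand-computed: chains (1,2,3,4) and (3,4,5,6); W = 5/3, B = 8,
  # varplus = 3/4 * 5/3 + 8/4 = 3.25, Rhat = sqrt(3.25 / (5/3))
  x <- cbind(1:4, 3:6)
  expect_equal(gelman_rubin(x), sqrt(3.25 / (5 / 3)), tolerance = 1e-12)

  # identical chains: exactly 1
  set.seed(1)
  y <- stats::rnorm(50)
  expect_equal(gelman_rubin(cbind(y, y)), 1)

  # chains with disjoint support: far above 1
  expect_gt(gelman_rubin(cbind(rep(0:1, 25), rep(10:11, 25))), 5)

  expect_error(gelman_rubin(matrix(1:10, 10, 1)), "two chains")
})

test_that("effective size: white noise, AR(1) closed form, constant chains", {
  set.seed(2)
  wn <- matrix(stats::rnorm(20000), ncol = 4)
  expect_equal(effective_size(wn), 20000, tolerance = 0.1)

  # AR(1) with rho = 0.9: N_eff ~ N (1 - rho) / (1 + rho)
  rho <- 0.9
  ar <- vapply(1:4, function(i) {
    as.numeric(stats::arima.sim(list(ar = rho), 10000))
  }, numeric(10000))
  expect_equal(effective_size(ar), 40000 * (1 - rho) / (1 + rho),
               tolerance = 0.25)

  # never exceeds the retained-draw cap
  expect_lte(effective_size(wn), 20000)

  expect_warning(ne <- effective_size(matrix(1, 50, 2)), "constant")
  expect_true(is.nan(ne))
})

test_that("summaries: degenerate draws, percentile convention, truth column", {
  d <- structure(list(
    group_names = "G1",
    combined = list(matrix(0.5, 100, 1, dimnames = list(NULL, "G1")),
                    matrix(0.5, 100, 1, dimnames = list(NULL, "G1")))
  ), class = "gsi_draws")
  expect_warning(s <- summary(d), "constant")
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower_90, s$upper_90), c(0.5, 0.5))

  # linear interpolation between order statistics on 11 equally spaced
  # points: the 5th/95th percentiles land halfway into the end gaps
  pts <- seq(0, 1, by = 0.1)
  expect_equal(unname(stats::quantile(pts, c(0.05, 0.95), type = 7)),
               c(0.05, 0.95))

  d2 <- structure(list(
    group_names = c("A", "B"),
    combined = list(
      matrix(c(pts, rev(pts)), 11, 2, dimnames = list(NULL, c("A", "B")))
    )
  ), class = "gsi_draws")
  s2 <- summary(d2, truth = c(A = 0.4, B = 0.6))
  expect_equal(s2$true, c(0.4, 0.6))
  expect_equal(s2$lower_90, c(0.05, 0.05))
  expect_equal(s2$upper_90, c(0.95, 0.95))
  expect_true(all(is.na(s2$rhat)))
})

test_that("evaluation metrics match their defining formulas", {
  expect_equal(rmse(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(bias(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(pct_deviation(c(0.2, 0.4), c(0.2, 0.4)), 0)

  tr <- c(0.2, 0.4); es <- c(0.3, 0.2)
  expect_equal(bias(tr, es), -0.05)
  expect_equal(rmse(tr, es), sqrt((0.01 + 0.04) / 2))
  expect_equal(pct_deviation(tr, es), 50)

  # an error of exactly the tolerance is not a deviation (strict >)
  expect_equal(pct_deviation(0.5, 0.6), 0)
  expect_equal(pct_deviation(0.5, 0.6000001), 100)

  # RMSE >= |bias| on arbitrary data
  set.seed(3)
  for (i in 1:25) {
    a <- stats::runif(7); b <- stats::runif(7)
    expect_gte(rmse(a, b), abs(bias(a, b)))
  }
})

test_that("draws flatten and round-trip through the CSV writer", {
  inst <- rand_tiny_instance(5, M = 2)
  fit <- run_msgsi(inst$mix_broad, inst$mix_regional, inst$broad_base,
                   inst$regional_bases, inst$rm,
                   mcmc = quick_mcmc(30, n_iter = 40, n_burn = 20))
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 2 * 20 * 3)  # chains x draws x groups
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, f)
  expect_equal(read_draws(f), df, tolerance = 1e-12)
})
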