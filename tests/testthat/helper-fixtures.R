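# Small hand-built instances used across the test files.

# a diallelic locus
loc <- function(name, alleles = c("A", "T"), ploidy = 2L) {
  locus_spec(name, alleles, ploidy)
}

# baseline from a per-locus list of count matrices (rows = pops)
make_baseline <- function(pops, loci, counts) {
  n <- vapply(seq_along(loci), function(l)
    as.integer(rowSums(counts[[l]]) / loci[[l]]$ploidy), integer(length(pops)))
  baseline_data(loci, pops, lapply(counts, function(m) {
    storage.mode(m) <- "integer"
    m
  }), matrix(n, nrow = length(pops)))
}

# mixture from a per-locus list of genotype count matrices (rows = fish)
make_mixture <- function(ids, loci, counts, observed = NULL) {
  mixture_data(loci, ids, lapply(counts, function(m) {
    storage.mode(m) <- "integer"
    m
  }), observed)
}

# A tiny two-stage world: broad pops P1 (group A, no region) and P2
# (group B, region r1); regional pops Q1/Q2 in groups Ba/Bb.  One
# diallelic locus per stage.  Counts chosen so markers are informative
# but not diagnostic.
tiny_region_map <- function() {
  region_map(
    broad_group_of = c(P1 = "A", P2 = "B"),
    region_of_group = c(B = "r1"),
    regional_group_of = list(r1 = c(Q1 = "Ba", Q2 = "Bb"))
  )
}

# random tiny multistage instance for oracle comparisons
rand_tiny_instance <- function(seed, M = 3) {
  set.seed(seed)
  broad_loci <- list(loc("L1"))
  reg_loci <- list(loc("R1", c("C", "G")))
  yb <- rbind(c(stats::rbinom(1, 10, 0.8)), c(stats::rbinom(1, 10, 0.2)))
  yb <- cbind(yb, 10 - yb)
  yr <- rbind(c(stats::rbinom(1, 10, 0.7)), c(stats::rbinom(1, 10, 0.3)))
  yr <- cbind(yr, 10 - yr)
  broad_base <- make_baseline(c("P1", "P2"), broad_loci, list(yb))
  reg_base <- make_baseline(c("Q1", "Q2"), reg_loci, list(yr))
  xb <- t(stats::rmultinom(M, 2, c(0.5, 0.5)))
  xr <- t(stats::rmultinom(M, 2, c(0.5, 0.5)))
  ids <- paste0("f", seq_len(M))
  list(
    mix_broad = make_mixture(ids, broad_loci, list(xb)),
    mix_regional = list(r1 = make_mixture(ids, reg_loci, list(xr))),
    broad_base = broad_base,
    regional_bases = list(r1 = reg_base),
    rm = tiny_region_map()
  )
}

# A fully diagnostic two-stage instance: every population carries a
# private allele at both stages, so assignments are certain.
diagnostic_instance <- function(M_per_pop = c(P1 = 4, Q1 = 3, Q2 = 3),
                                n_base = 10) {
  broad_loci <- list(loc("L1", c("A", "C", "G")))
  reg_loci <- list(loc("R1", c("A", "C", "G")))
  # broad pops: P1 fixed for A; P2 fixed for C; regional fish carry C
  # at the broad locus (they belong to P2's area) and their own private
  # allele at the regional locus
  broad_base <- make_baseline(
    c("P1", "P2"), broad_loci,
    list(rbind(c(2 * n_base, 0, 0), c(0, 2 * n_base, 0)))
  )
  reg_base <- make_baseline(
    c("Q1", "Q2"), reg_loci,
    list(rbind(c(2 * n_base, 0, 0), c(0, 2 * n_base, 0)))
  )
  counts <- c(P1 = M_per_pop[["P1"]], Q1 = M_per_pop[["Q1"]],
              Q2 = M_per_pop[["Q2"]])
  M <- sum(counts)
  ids <- paste0("f", seq_len(M))
  src <- rep(names(counts), counts)
  xb <- matrix(0L, M, 3)
  xb[src == "P1", 1] <- 2L
  xb[src != "P1", 2] <- 2L   # regional fish look like P2 at the broad locus
  xr <- matrix(0L, M, 3)
  xr[src == "Q1", 1] <- 2L
  xr[src == "Q2", 2] <- 2L
  xr[src == "P1", 3] <- 2L   # non-regional fish carry an allele alien to r1
  list(
    mix_broad = make_mixture(ids, broad_loci, list(xb)),
    mix_regional = list(r1 = make_mixture(ids, reg_loci, list(xr))),
    broad_base = broad_base,
    regional_bases = list(r1 = reg_base),
    rm = tiny_region_map(),
    truth = c(A = counts[["P1"]] / M, Ba = counts[["Q1"]] / M,
              Bb = counts[["Q2"]] / M),
    source = src
  )
}

# short MCMC schedule for unit tests
quick_mcmc <- function(seed, n_chains = 2, n_iter = 600, n_burn = 300,
                       thin = 1, ...) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
              thin = thin, seed = seed, ...)
}
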