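# Independent brute-force oracle for tiny conditional-model instances:
# enumerates every joint membership configuration (broad and regional),
# weights each by its exact unnormalized posterior probability with the
# proportion vectors integrated out analytically, and returns the exact
# posterior mean of the combined reporting-group proportions.  Everything
# here is computed from first principles (lgamma arithmetic), not through
# the package's sampling code.

# compound Dirichlet-multinomial pmf (with coefficient)
oracle_cdm <- function(x, v) {
  exp(lgamma(sum(x) + 1) - sum(lgamma(x + 1)) +
        lgamma(sum(v)) - lgamma(sum(v) + sum(x)) +
        sum(lgamma(v + x) - lgamma(v)))
}

# Dirichlet-multinomial marginal of a count configuration under prior alpha
oracle_dirmult <- function(counts, alpha) {
  exp(lgamma(sum(alpha)) - lgamma(sum(alpha) + sum(counts)) +
        sum(lgamma(alpha + counts) - lgamma(alpha)))
}

# per-fish x per-population CDM likelihood table for one stage
oracle_lik_table <- function(mix, base) {
  M <- length(mix$individuals)
  K <- length(base$populations)
  out <- matrix(1, M, K)
  for (l in seq_along(base$loci)) {
    J <- length(base$loci[[l]]$alleles)
    for (k in seq_len(K)) {
      v <- base$counts[[l]][k, ] + 1 / J
      for (m in seq_len(M)) {
        if (mix$observed[m, l]) {
          out[m, k] <- out[m, k] * oracle_cdm(mix$counts[[l]][m, ], v)
        }
      }
    }
  }
  out
}

# group-flat prior weights, recomputed independently of the package
oracle_alpha <- function(pops, group_of) {
  g <- unname(group_of[pops])
  gl <- unique(g)
  sapply(g, function(x) (1 / length(gl)) / sum(g == x))
}

# Exact long-run mean of the combined group proportions for a tiny
# multistage instance (single region, two broad populations, two regional
# populations, conditional model, group-flat prior).
#
# The sweep draws, per iteration: broad memberships z | p, regional
# memberships z_r | p_r for the fish currently assigned inside the region,
# then fresh p | z and p_r | z_r.  Because each proportion vector is
# regenerated from the current counts alone, the membership pair (z, z_r)
# is a finite-state Markov chain whose transition probabilities are
# one-dimensional Beta integrals (B = K_r = 2).  We build that kernel by
# numeric quadrature, find its stationary distribution by power iteration,
# and average the closed-form conditional means of p and p_r over it.
# This reproduces the algorithm's exact stationary law, including the fact
# that the broad stage is unaffected by regional data (one-way linkage)
# and that the regional draw conditions on the previous sweep's p_r.
oracle_msgsi_means <- function(mix_broad, mix_regional, broad_base,
                               regional_base, rm) {
  r <- names(rm$regional_group_of)[1]
  pops_b <- broad_base$populations
  pops_r <- regional_base$populations
  stopifnot(length(pops_b) == 2, length(pops_r) == 2)
  M <- length(mix_broad$individuals)
  alpha_b <- oracle_alpha(pops_b, rm$broad_group_of)
  alpha_r <- oracle_alpha(pops_r, rm$regional_group_of[[r]])
  lik_b <- oracle_lik_table(mix_broad, broad_base)
  lik_r <- oracle_lik_table(mix_regional[[r]], regional_base)
  br <- which(unname(rm$broad_group_of[pops_b]) %in%
                names(rm$region_of_group)[rm$region_of_group == r])

  # probability of drawing memberships `znew` for the fish in `who` when
  # the 2-component proportion vector is Beta(a[1], a[2])-distributed
  trans_prob <- function(znew, who, lik, a) {
    if (length(who) == 0) return(1)
    f <- function(p1) {
      out <- rep(1, length(p1))
      for (i in seq_along(who)) {
        m <- who[i]
        w1 <- p1 * lik[m, 1]
        w2 <- (1 - p1) * lik[m, 2]
        out <- out * (if (znew[i] == 1) w1 else w2) / (w1 + w2)
      }
      out * stats::dbeta(p1, a[1], a[2])
    }
    stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }

  # state space: broad memberships x regional memberships of eligible fish
  z_grid <- as.matrix(expand.grid(rep(list(1:2), M)))
  states <- list()
  for (zi in seq_len(nrow(z_grid))) {
    z <- as.integer(z_grid[zi, ])
    elig <- which(z %in% br)
    zr_grid <- if (length(elig) == 0) matrix(integer(0), 1, 0) else
      as.matrix(expand.grid(rep(list(1:2), length(elig))))
    for (ri in seq_len(nrow(zr_grid))) {
      zr <- rep(NA_integer_, M)
      zr[elig] <- as.integer(zr_grid[ri, ])
      states[[length(states) + 1L]] <- list(z = z, zr = zr, elig = elig)
    }
  }
  S <- length(states)

  K <- matrix(0, S, S)
  for (si in seq_len(S)) {
    s <- states[[si]]
    a_b <- tabulate(s$z, 2) + alpha_b
    a_r <- tabulate(s$zr[!is.na(s$zr)], 2) + alpha_r
    for (sj in seq_len(S)) {
      s2 <- states[[sj]]
      pb <- trans_prob(s2$z, seq_len(M), lik_b, a_b)
      pr <- trans_prob(s2$zr[s2$elig], s2$elig, lik_r, a_r)
      K[si, sj] <- pb * pr
    }
  }
  stopifnot(max(abs(rowSums(K) - 1)) < 1e-6)
  K <- K / rowSums(K)

  pi_s <- rep(1 / S, S)
  for (i in 1:5000) pi_s <- pi_s %*% K
  pi_s <- as.numeric(pi_s / sum(pi_s))

  nonreg <- setdiff(unique(unname(rm$broad_group_of)),
                    names(rm$region_of_group))
  rgroups <- unique(unname(rm$regional_group_of[[r]]))
  gnames <- c(nonreg, rgroups)
  acc <- stats::setNames(numeric(length(gnames)), gnames)
  for (si in seq_len(S)) {
    s <- states[[si]]
    Ep <- (tabulate(s$z, 2) + alpha_b) / (M + sum(alpha_b))
    n_el <- length(s$elig)
    Epr <- (tabulate(s$zr[!is.na(s$zr)], 2) + alpha_r) /
      (n_el + sum(alpha_r))
    contrib <- stats::setNames(numeric(length(gnames)), gnames)
    for (g in nonreg) {
      contrib[g] <- sum(Ep[unname(rm$broad_group_of[pops_b]) == g])
    }
    reg_total <- sum(Ep[br])
    for (g in rgroups) {
      contrib[g] <- reg_total *
        sum(Epr[unname(rm$regional_group_of[[r]][pops_r]) == g])
    }
    acc <- acc + pi_s[si] * contrib
  }
  acc
}

# Naive fully-factorized enumeration (broad posterior times regional
# posterior given eligibility), kept for comparison in the vignette
# discussion of the one-way linkage; the Markov oracle above is the exact
# reference for the algorithm as specified.
oracle_factorized_means <- function(mix_broad, mix_regional, broad_base,
                                    regional_base, rm) {
  r <- names(rm$regional_group_of)[1]
  pops_b <- broad_base$populations
  pops_r <- regional_base$populations
  M <- length(mix_broad$individuals)
  B <- length(pops_b)
  Kr <- length(pops_r)
  alpha_b <- oracle_alpha(pops_b, rm$broad_group_of)
  alpha_r <- oracle_alpha(pops_r, rm$regional_group_of[[r]])
  lik_b <- oracle_lik_table(mix_broad, broad_base)
  lik_r <- oracle_lik_table(mix_regional[[r]], regional_base)
  br <- which(unname(rm$broad_group_of[pops_b]) %in%
                names(rm$region_of_group)[rm$region_of_group == r])

  nonreg <- setdiff(unique(unname(rm$broad_group_of)),
                    names(rm$region_of_group))
  rgroups <- unique(unname(rm$regional_group_of[[r]]))
  gnames <- c(nonreg, rgroups)
  acc <- stats::setNames(numeric(length(gnames)), gnames)
  tot_w <- 0

  z_grid <- expand.grid(rep(list(seq_len(B)), M))
  for (zi in seq_len(nrow(z_grid))) {
    z <- as.integer(z_grid[zi, ])
    w_b <- prod(lik_b[cbind(seq_len(M), z)]) *
      oracle_dirmult(tabulate(z, B), alpha_b)
    cb <- tabulate(z, B)
    Ep <- (cb + alpha_b) / (M + sum(alpha_b))
    elig <- which(z %in% br)
    n_el <- length(elig)

    # regional posterior given this broad configuration, normalized on
    # its own (the broad stage sees no regional information)
    zr_grid <- if (n_el == 0) matrix(integer(0), 1, 0) else
      as.matrix(expand.grid(rep(list(seq_len(Kr)), n_el)))
    inner <- stats::setNames(numeric(length(rgroups)), rgroups)
    inner_w <- 0
    for (ri in seq_len(nrow(zr_grid))) {
      zr <- as.integer(zr_grid[ri, ])
      w_r <- if (n_el == 0) 1 else
        prod(lik_r[cbind(elig, zr)]) *
          oracle_dirmult(tabulate(zr, Kr), alpha_r)
      Epr <- (tabulate(zr, Kr) + alpha_r) / (n_el + sum(alpha_r))
      for (g in rgroups) {
        inner[g] <- inner[g] + w_r *
          sum(Epr[unname(rm$regional_group_of[[r]][pops_r]) == g])
      }
      inner_w <- inner_w + w_r
    }
    inner <- inner / inner_w

    contrib <- stats::setNames(numeric(length(gnames)), gnames)
    for (g in nonreg) {
      contrib[g] <- sum(Ep[unname(rm$broad_group_of[pops_b]) == g])
    }
    # E[p_r,g * sum_{b in Br} p_b] factorizes: given the memberships the
    # two Dirichlet vectors are independent
    reg_total <- sum(Ep[br])
    for (g in rgroups) contrib[g] <- reg_total * inner[g]
    acc <- acc + w_b * contrib
    tot_w <- tot_w + w_b
  }
  acc / tot_w
}

# Exact posterior mean of group proportions for a tiny single-baseline
# conditional instance (enumeration over broad memberships only).
oracle_single_means <- function(mix, base, group_of) {
  pops <- base$populations
  M <- length(mix$individuals)
  K <- length(pops)
  alpha <- oracle_alpha(pops, group_of)
  lik <- oracle_lik_table(mix, base)
  gnames <- unique(unname(group_of[pops]))
  acc <- stats::setNames(numeric(length(gnames)), gnames)
  tot_w <- 0
  z_grid <- expand.grid(rep(list(seq_len(K)), M))
  for (zi in seq_len(nrow(z_grid))) {
    z <- as.integer(z_grid[zi, ])
    w <- prod(lik[cbind(seq_len(M), z)]) *
      oracle_dirmult(tabulate(z, K), alpha)
    Ep <- (tabulate(z, K) + alpha) / (M + sum(alpha))
    for (g in gnames) {
      acc[g] <- acc[g] + w * sum(Ep[unname(group_of[pops]) == g])
    }
    tot_w <- tot_w + w
  }
  acc / tot_w
}

# Monte-Carlo standard error of each group's posterior mean.  Two
# estimates are combined (their max): the spread of per-chain means, and
# the pooled spread scaled by the autocorrelation-adjusted effective size;
# with few chains either alone can understate the error.
mc_se <- function(fit) {
  cm <- vapply(fit$combined, colMeans, numeric(length(fit$group_names)))
  cm <- matrix(cm, ncol = length(fit$combined))
  se_chain <- apply(cm, 1, stats::sd) / sqrt(ncol(cm))
  se_neff <- vapply(seq_along(fit$group_names), function(g) {
    ch <- vapply(fit$combined, function(m) m[, g],
                 numeric(nrow(fit$combined[[1]])))
    stats::sd(as.vector(ch)) / sqrt(effective_size(ch))
  }, numeric(1))
  pmax(se_chain, se_neff)
}
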