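# Full-conditional building blocks of the Gibbs sampler.  These are exported
# both as user-visible primitives and because the tests check their exact
# distributions against closed forms.

#' Draw individual memberships from their full conditional
#'
#' For each mixture individual, draws a population membership with
#' probability proportional to `p_k * exp(log_lik[m, k])`, normalized
#' stably in the log domain (the row maximum is subtracted before
#' exponentiating).
#'
#' @param log_lik Matrix of log genotype likelihoods, individuals x
#'   populations (see [log_genotype_likelihood()]).
#' @param p Current mixture proportion vector (simplex of length K).
#' @return Integer vector of population indices, one per individual.
#' @export
sample_memberships <- function(log_lik, p) {
  stopifnot(ncol(log_lik) == length(p))
  M <- nrow(log_lik)
  if (M == 0L) return(integer(0))
  W <- log_lik + rep(log(p), each = M)
  mx <- W[cbind(seq_len(M), max.col(W, ties.method = "first"))]
  dead <- !is.finite(mx)
  if (any(dead)) {
    ids <- rownames(log_lik)[dead] %||% which(dead)
    stop("individual(s) with zero likelihood under every population ",
         "(check marker registries): ", paste(utils::head(ids, 5), collapse = ", "))
  }
  P <- exp(W - mx)
  # row-wise cumulative sums via an upper-triangular product, then inverse CDF
  Cm <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  u <- stats::runif(M) * Cm[, ncol(Cm)]
  as.integer(rowSums(Cm < u) + 1L)
}

#' Draw mixture proportions from their full conditional
#'
#' Dirichlet draw with parameter `counts + alpha`, the conjugate update of
#' the proportion prior by the current membership counts.
#'
#' @param counts Integer vector of individuals currently assigned to each
#'   population (zero everywhere gives a pure prior draw).
#' @param alpha Positive Dirichlet prior weights.
#' @return A simplex vector.
#' @export
sample_proportions <- function(counts, alpha) {
  stopifnot(length(counts) == length(alpha), all(alpha > 0))
  rdirichlet1(counts + alpha)
}

#' Draw baseline allele frequencies from their full conditional
#'
#' Fully Bayesian model only: per population and locus, a Dirichlet draw
#' with parameter `y + beta + (mixture counts of currently assigned fish)`.
#' The conditional model never calls this (its posterior-predictive weights
#' `v = beta + y` are fixed at the start of the run).
#'
#' @param base A [baseline_data()].
#' @param mix Optional [mixture_data()] aligned to the baseline.
#' @param z Optional integer membership vector (from
#'   [sample_memberships()]); fish counts are added to their assigned
#'   population.  With `mix = NULL`, the draw conditions on the baseline
#'   alone (or on the prior alone if the baseline has zero counts).
#' @param beta Per-locus allele prior weights; default `1/J_l`.
#' @return Per-locus list of K x J frequency matrices (rows sum to 1).
#' @export
sample_allele_freqs <- function(base, mix = NULL, z = NULL, beta = NULL) {
  beta <- beta %||% default_beta(base$loci)
  K <- length(base$populations)
  lapply(seq_along(base$loci), function(l) {
    par <- base$counts[[l]] +
      matrix(beta[[l]], K, length(base$loci[[l]]$alleles), byrow = TRUE)
    if (!is.null(mix) && !is.null(z) && length(z)) {
      agg <- rowsum(mix$counts[[l]], z)  # only populations with fish
      add <- matrix(0, K, ncol(par))
      add[as.integer(rownames(agg)), ] <- agg
      par <- par + add
    }
    t(apply(par, 1, rdirichlet1))
  })
}

# Lean categorical draw used inside the chain loop: adds standard Gumbel
# noise to the log weights and takes the row-wise argmax, which draws from
# exactly the normalized-weight distribution of sample_memberships()
# without forming the normalization explicitly.
draw_members <- function(logL, logp) {
  M <- nrow(logL)
  W <- logL + rep(logp, each = M) -
    log(-log(stats::runif(length(logL))))
  max.col(W, ties.method = "first")
}

# check-free single Dirichlet draw for the chain loop
dir_draw <- function(a) {
  g <- stats::rgamma(length(a), a)
  s <- sum(g)
  if (s <= 0) {
    g[which.max(a)] <- 1
    s <- 1
  }
  g / s
}

# ---- stage preparation ------------------------------------------------------

# alpha over a baseline's populations under a prior_spec
build_alpha <- function(populations, group_of, prior) {
  g <- unname(group_of[populations])
  if (anyNA(g)) {
    stop("population(s) missing from the group map: ",
         paste(populations[is.na(g)], collapse = ", "))
  }
  if (!is.null(prior$alpha)) {
    a <- prior$alpha[populations]
    if (anyNA(a)) stop("prior$alpha must name every baseline population")
    return(unname(a))
  }
  if (prior$alpha_mode == "per_population_flat") {
    rep(1 / length(populations), length(populations))
  } else {
    groups <- unique(g)
    per_group <- 1 / length(groups)
    as.numeric(per_group / table(g)[g])
  }
}

# Everything one stage of the sampler needs, precomputed.
prep_stage <- function(mix, base, group_of, prior, model) {
  al <- align_mixture_to_baseline(mix, base)
  beta <- resolve_beta(prior, al$baseline$loci)
  st <- list(
    mix = al$mixture,
    base = al$baseline,
    beta = beta,
    alpha = build_alpha(al$baseline$populations, group_of, prior),
    groups = unname(group_of[al$baseline$populations]),
    K = length(al$baseline$populations),
    M = length(al$mixture$individuals)
  )
  if (model == "conditional") {
    st$logL <- loglik_table_cdm(st$mix, st$base, beta)
    if (st$M > 0 && any(!is.finite(apply(st$logL, 1, max)))) {
      bad <- which(!is.finite(apply(st$logL, 1, max)))
      stop("individual(s) with zero likelihood under every population: ",
           paste(utils::head(st$mix$individuals[bad], 5), collapse = ", "))
    }
  }
  # group indicator for aggregating population draws
  gl <- unique(st$groups)
  st$group_names <- gl
  st$G <- outer(st$groups, gl, `==`) + 0
  st
}

# ---- one chain of the (multi)stage sampler ---------------------------------

# broad: prep_stage() output; regs: named list of prep_stage() outputs with
# an extra $br_idx (indices of broad populations belonging to the region).
# Returns retained draws for this chain.
run_chain <- function(broad, regs, mcmc) {
  if (mcmc$model == "conditional") {
    res <- .gibbs_chain_cond(
      broad$logL,
      lapply(regs, `[[`, "logL"),
      lapply(regs, function(s) as.integer(s$br_idx)),
      as.numeric(broad$alpha),
      lapply(regs, function(s) as.numeric(s$alpha)),
      mcmc$n_iter, mcmc$n_burn, mcmc$thin,
      isTRUE(mcmc$record_memberships)
    )
    return(res)
  }
  n_keep <- retained_draws(mcmc, per_chain = TRUE)
  M <- broad$M
  B <- broad$K
  fully <- mcmc$model == "fully_bayesian"

  P <- matrix(NA_real_, n_keep, B)
  Preg <- lapply(regs, function(s) matrix(NA_real_, n_keep, s$K))
  z_hits <- matrix(0L, M, B)
  zrec <- if (isTRUE(mcmc$record_memberships))
    matrix(NA_integer_, n_keep, M) else NULL

  # initial values drawn from the priors
  p <- rdirichlet1(broad$alpha)
  p_reg <- lapply(regs, function(s) rdirichlet1(s$alpha))
  if (fully) {
    q <- sample_allele_freqs(zero_counts(broad$base), beta = broad$beta)
    q_reg <- lapply(regs, function(s)
      sample_allele_freqs(zero_counts(s$base), beta = s$beta))
  }

  keep <- 0L
  for (t in seq_len(mcmc$n_iter)) {
    logL <- if (fully) loglik_table_q(broad$mix, q) else broad$logL
    z <- draw_members(logL, log(p))

    # regional memberships, only for fish whose current broad assignment
    # falls inside the region; ineligible fish are rebuilt from scratch
    # every sweep (their membership is the zero vector)
    zr <- vector("list", length(regs))
    elig <- vector("list", length(regs))
    for (r in seq_along(regs)) {
      s <- regs[[r]]
      e <- z %in% s$br_idx
      elig[[r]] <- e
      if (any(e)) {
        logLr <- if (fully) loglik_table_q(subset_mix_rows(s$mix, e), q_reg[[r]])
                 else s$logL[e, , drop = FALSE]
        zr[[r]] <- draw_members(logLr, log(p_reg[[r]]))
      } else {
        zr[[r]] <- integer(0)
      }
    }

    p <- dir_draw(tabulate(z, B) + broad$alpha)
    for (r in seq_along(regs)) {
      p_reg[[r]] <- dir_draw(tabulate(zr[[r]], regs[[r]]$K) + regs[[r]]$alpha)
    }
    if (fully) {
      q <- sample_allele_freqs(broad$base, broad$mix, z, broad$beta)
      for (r in seq_along(regs)) {
        s <- regs[[r]]
        q_reg[[r]] <- sample_allele_freqs(
          s$base, subset_mix_rows(s$mix, elig[[r]]), zr[[r]], s$beta)
      }
    }

    if (t > mcmc$n_burn && (t - mcmc$n_burn) %% mcmc$thin == 0L) {
      keep <- keep + 1L
      P[keep, ] <- p
      for (r in seq_along(regs)) Preg[[r]][keep, ] <- p_reg[[r]]
      if (M > 0) z_hits[cbind(seq_len(M), z)] <- z_hits[cbind(seq_len(M), z)] + 1L
      if (!is.null(zrec)) zrec[keep, ] <- z
    }
  }
  list(p = P, p_reg = Preg, z_hits = z_hits, memberships = zrec)
}

# baseline with all counts zeroed: prior-only frequency draws
zero_counts <- function(base) {
  base$counts <- lapply(base$counts, function(m) m * 0L)
  base$sample_sizes <- base$sample_sizes * 0L
  base
}

subset_mix_rows <- function(mix, keep) {
  mixture_data(mix$loci, mix$individuals[keep],
               lapply(mix$counts, function(m) m[keep, , drop = FALSE]),
               mix$observed[keep, , drop = FALSE])
}

#' Single-baseline Bayesian GSI (Pella-Masuda / conditional)
#'
#' Runs the classic one-baseline mixture sampler: individuals are assigned
#' to baseline populations and population proportions are drawn from their
#' Dirichlet full conditional, over several independent chains initialized
#' from the priors.  Reporting-group proportions are the sums of their
#' member populations' proportions at every retained iteration.
#'
#' @param mix A [mixture_data()].
#' @param base A [baseline_data()].
#' @param groups Named character vector mapping every baseline population
#'   to its reporting group.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A [gsi_draws] object.
#' @seealso [run_msgsi()] for the integrated multistage sampler.
#' @export
run_single_gsi <- function(mix, base, groups, prior = prior_spec(),
                           mcmc = mcmc_config()) {
  rm <- region_map(broad_group_of = groups)
  run_msgsi(mix_broad = mix, mix_regional = list(), broad_base = base,
            regional_bases = list(), region_map = rm, prior = prior,
            mcmc = mcmc)
}
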