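# The integrated multistage sampler: a broad-scale mixture model and one
# regional mixture model per sub-region, linked inside each Gibbs iteration.
# A fish only enters region r's stage during iterations in which its current
# broad-scale assignment falls in B_r (the broad populations of that
# region); its regional membership is otherwise the zero vector.  Because
# both stages live in one sampler, assignment uncertainty at the broad
# scale propagates into the regional proportion estimates.

#' Which fish are eligible for each regional stage
#'
#' @param z Integer vector of current broad-scale population assignments.
#' @param rm A [region_map()].
#' @param populations Broad-baseline population names (the index space of
#'   `z`).
#' @return Logical matrix, individuals x regions.  Row sums are at most 1
#'   because sub-regions are disjoint.
#' @export
regional_eligibility <- function(z, rm, populations) {
  regions <- region_ids(rm)
  out <- matrix(FALSE, length(z), length(regions),
                dimnames = list(NULL, regions))
  for (r in seq_along(regions)) {
    br <- br_indices(rm, regions[r], populations)
    out[, r] <- z %in% br
  }
  out
}

# indices (into `populations`) of broad populations belonging to region r
br_indices <- function(rm, r, populations) {
  gr <- groups_in_region(rm, r)
  which(unname(rm$broad_group_of[populations]) %in% gr)
}

#' Draw regional memberships for the eligible fish
#'
#' Eligible fish draw a regional population from weights proportional to
#' `p_r[k] * exp(log_lik[m, k])`; ineligible fish keep the zero membership
#' vector (encoded as `NA`).
#'
#' @param log_lik Regional log-likelihood table, all individuals x regional
#'   populations.
#' @param p_r Current regional proportion vector.
#' @param eligible Logical vector over individuals.
#' @return Integer vector with regional population indices for eligible
#'   fish and `NA` elsewhere.
#' @export
sample_regional_memberships <- function(log_lik, p_r, eligible) {
  out <- rep(NA_integer_, length(eligible))
  if (any(eligible)) {
    out[eligible] <- sample_memberships(log_lik[eligible, , drop = FALSE], p_r)
  }
  out
}

#' Draw regional proportions from their full conditional
#'
#' Dirichlet draw with parameter `counts + alpha_r`, where the counts come
#' from the currently eligible fish only; with no eligible fish this is a
#' pure prior draw.
#'
#' @param zr Regional membership vector (`NA` = ineligible), or an integer
#'   count vector when `counts = TRUE` semantics are preferred.
#' @param K_r Number of regional populations.
#' @param alpha_r Regional Dirichlet prior weights.
#' @return A simplex vector of length `K_r`.
#' @export
sample_regional_proportions <- function(zr, K_r, alpha_r) {
  sample_proportions(tabulate(zr[!is.na(zr)], K_r), alpha_r)
}

#' Combine broad and regional proportions into one reporting vector
#'
#' Broad reporting groups with no regional baseline keep their broad-stage
#' proportion; each regional reporting group gets its regional proportion
#' scaled by the total broad-stage proportion of its region,
#' `p_r[g] * sum(p[b in B_r])`.  The result sums to one whenever the
#' inputs are simplexes.
#'
#' @param p_broad Named simplex over broad reporting groups.
#' @param p_regional Named list (by region id) of named simplexes over
#'   regional reporting groups.
#' @param rm A [region_map()].
#' @return Named vector over the combined reporting groups.
#' @examples
#' rm <- region_map(c(p1 = "A", p2 = "B", p3 = "C"), c(C = "yuk"),
#'                  list(yuk = c(r1 = "Ca", r2 = "Cb")))
#' combine_proportions(c(A = 0.2, B = 0.3, C = 0.5),
#'                     list(yuk = c(Ca = 0.4, Cb = 0.6)), rm)
#' @export
combine_proportions <- function(p_broad, p_regional, rm) {
  out <- p_broad[nonregional_groups(rm)]
  for (r in region_ids(rm)) {
    scale <- sum(p_broad[groups_in_region(rm, r)])
    out <- c(out, p_regional[[r]] * scale)
  }
  out
}

#' Integrated multistage genetic stock identification
#'
#' Fits the two-stage mixture model in a single Gibbs sampler.  Per
#' iteration: (a) every fish draws a broad-scale population membership;
#' (b) for each region, fish currently assigned inside the region draw a
#' regional membership; (c) broad and regional proportion vectors are
#' drawn from their Dirichlet full conditionals (and allele frequencies
#' too, under the fully Bayesian model).  The combined reporting-group
#' vector - non-regional broad groups at their broad proportion, regional
#' groups at their regional proportion scaled by the region's broad total -
#' is recorded at every retained iteration.
#'
#' Every mixture fish must be genotyped (missing loci allowed) on every
#' baseline's marker set; the baselines themselves need share no loci or
#' populations.  With an empty region map this reduces exactly to
#' [run_single_gsi()], bit-identically at matched seeds.
#'
#' @param mix_broad [mixture_data()] at the broad-scale markers.
#' @param mix_regional Named list (by region id) of [mixture_data()] at
#'   each regional marker set; same individuals, same order, as
#'   `mix_broad`.
#' @param broad_base Broad-scale [baseline_data()].
#' @param regional_bases Named list (by region id) of regional
#'   [baseline_data()].
#' @param region_map A [region_map()].
#' @param prior A [prior_spec()].  Regional prior weights are normalized
#'   within each region (unit total), so a zero-eligibility iteration
#'   draws from a proper prior.
#' @param mcmc An [mcmc_config()].
#' @return A [gsi_draws] object; see [summary.gsi_draws()].
#' @export
run_msgsi <- function(mix_broad, mix_regional = list(), broad_base,
                      regional_bases = list(), region_map,
                      prior = prior_spec(), mcmc = mcmc_config()) {
  rm <- region_map
  validate_region_map(rm)
  regions <- region_ids(rm)
  missing_base <- setdiff(regions, names(regional_bases))
  if (length(missing_base)) {
    stop("region(s) in the map without a regional baseline: ",
         paste(missing_base, collapse = ", "))
  }
  missing_mix <- setdiff(regions, names(mix_regional))
  if (length(missing_mix)) {
    stop("region(s) without a regional mixture: ",
         paste(missing_mix, collapse = ", "))
  }
  for (r in regions) {
    if (!identical(mix_regional[[r]]$individuals, mix_broad$individuals)) {
      stop("regional mixture '", r, "' must contain the same individuals, ",
           "in the same order, as the broad mixture")
    }
  }

  broad <- prep_stage(mix_broad, broad_base, rm$broad_group_of, prior,
                      mcmc$model)
  regs <- lapply(regions, function(r) {
    s <- prep_stage(mix_regional[[r]], regional_bases[[r]],
                    rm$regional_group_of[[r]], prior, mcmc$model)
    s$br_idx <- br_indices(rm, r, broad$base$populations)
    if (length(s$br_idx) == 0L) {
      stop("region '", r, "' matches no broad-baseline population")
    }
    s
  })
  names(regs) <- regions

  seed <- mcmc$seed %||% sample.int(2147483646L, 1)
  chain_seeds <- derive_seeds(seed, mcmc$n_chains)
  chains <- lapply(seq_len(mcmc$n_chains), function(i) {
    with_seed(chain_seeds[i], run_chain(broad, regs, mcmc))
  })

  finalize_draws(chains, broad, regs, rm, mcmc, chain_seeds)
}

# assemble per-chain raw draws into a gsi_draws object
finalize_draws <- function(chains, broad, regs, rm, mcmc, chain_seeds) {
  regions <- names(regs)
  group_names <- combined_group_names(rm)
  nonreg <- nonregional_groups(rm)

  combined <- lapply(chains, function(ch) {
    bg <- ch$p %*% broad$G                       # T x broad groups
    colnames(bg) <- broad$group_names
    parts <- list(bg[, nonreg, drop = FALSE])
    for (r in seq_along(regs)) {
      s_r <- rowSums(bg[, groups_in_region(rm, regions[r]), drop = FALSE])
      rg <- ch$p_reg[[r]] %*% regs[[r]]$G
      colnames(rg) <- regs[[r]]$group_names
      parts[[r + 1L]] <- rg * s_r
    }
    out <- do.call(cbind, parts)
    out[, group_names, drop = FALSE]
  })

  broad_group <- lapply(chains, function(ch) {
    bg <- ch$p %*% broad$G
    colnames(bg) <- broad$group_names
    bg
  })

  structure(
    list(
      group_names = group_names,
      combined = combined,
      broad_group = broad_group,
      pop = lapply(chains, function(ch) {
        colnames(ch$p) <- broad$base$populations; ch$p
      }),
      regional_pop = stats::setNames(lapply(seq_along(regs), function(r) {
        lapply(chains, function(ch) {
          m <- ch$p_reg[[r]]; colnames(m) <- regs[[r]]$base$populations; m
        })
      }), regions),
      z_hits = Reduce(`+`, lapply(chains, `[[`, "z_hits")),
      memberships = if (isTRUE(mcmc$record_memberships))
        lapply(chains, `[[`, "memberships") else NULL,
      individuals = broad$mix$individuals,
      broad_pops = broad$base$populations,
      broad_groups = broad$group_names,
      region_map = rm,
      mcmc = mcmc,
      chain_seeds = chain_seeds
    ),
    class = "gsi_draws"
  )
}
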