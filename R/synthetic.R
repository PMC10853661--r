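# Synthetic baselines and leave-out mixtures with the structure of a
# two-stage GSI study: a broad-scale baseline covering every population at
# a small, weakly resolving marker set, and per-region baselines covering
# the region's populations at a larger, highly resolving marker set.
# Population allele frequencies follow an F-model: each locus has an
# ancestral frequency vector drawn flat, and each population drifts around
# it with concentration theta (smaller theta = stronger drift = more
# informative markers).  Baselines are generated as individual fish so that
# mixtures can be synthesized by leave-out draws and the drawn fish removed
# from the baselines, exactly as in a cross-validation study.

#' Describe a synthetic two-stage GSI study
#'
#' Defaults are a desk-scale analogue of a North-Pacific salmon case:
#' five reporting groups (one coastal group with no regional baseline and
#' four river groups covered by one regional baseline), a 205-fish
#' mixture at proportions (0.27, 0.10, 0.19, 0.13, 0.31), 10 broad-scale
#' and 40 regional markers, and 50 baseline fish per population.
#'
#' @param nonregional_groups Character vector of broad reporting groups
#'   with no regional baseline.
#' @param regional_groups Named list: region id -> character vector of the
#'   region's reporting groups.
#' @param pops_per_group Populations per non-regional group.
#' @param regional_pops_per_group Populations per regional group.
#' @param n_broad_loci,n_regional_loci Marker counts per stage.
#' @param n_alleles Alleles per locus (2 = SNP-like).
#' @param ploidy Copies per locus per fish.
#' @param baseline_n Baseline fish per population.
#' @param theta_broad,theta_regional F-model concentrations per stage;
#'   must be positive, smaller values give stronger differentiation.
#' @param mixture_size Number of mixture fish, M.
#' @param true_group_proportions Default true reporting-group proportions
#'   (non-regional groups first, then each region's groups); must sum to 1.
#' @param confuse Optional `list(group =, weight =)`: blend the named
#'   regional group's populations' broad-marker frequencies toward matched
#'   non-regional populations' frequencies by `weight` in (0, 1), making
#'   that group partially confusable with the non-regional group at the
#'   broad stage (its fish draw mid-range stage-1 assignment
#'   probabilities, and some non-regional fish look weakly regional).
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(nonregional_groups = "Coastal",
                               regional_groups = list(
                                 Upriver = c("LowerTrib", "MidTrib",
                                             "UpperTrib", "Headwaters")),
                               pops_per_group = 5L,
                               regional_pops_per_group = 4L,
                               n_broad_loci = 10L,
                               n_regional_loci = 40L,
                               n_alleles = 2L,
                               ploidy = 2L,
                               baseline_n = 50L,
                               theta_broad = 0.3,
                               theta_regional = 0.3,
                               mixture_size = 205L,
                               true_group_proportions =
                                 c(0.27, 0.10, 0.19, 0.13, 0.31),
                               confuse = NULL) {
  groups <- c(nonregional_groups,
              unlist(regional_groups, use.names = FALSE))
  if (anyDuplicated(groups)) stop("reporting-group names must be unique")
  stopifnot(pops_per_group >= 1, regional_pops_per_group >= 1,
            n_broad_loci >= 1, n_regional_loci >= 1, n_alleles >= 2,
            ploidy >= 1, baseline_n >= 1, mixture_size >= 1)
  if (theta_broad <= 0 || theta_regional <= 0) {
    stop("theta must be strictly positive")
  }
  if (length(true_group_proportions) != length(groups)) {
    stop("true_group_proportions must have one entry per reporting group (",
         length(groups), ")")
  }
  if (abs(sum(true_group_proportions) - 1) > 1e-8 ||
      any(true_group_proportions < 0)) {
    stop("true_group_proportions must be non-negative and sum to 1")
  }
  if (!is.null(confuse)) {
    stopifnot(is.list(confuse),
              confuse$group %in% unlist(regional_groups),
              confuse$weight > 0, confuse$weight < 1)
  }
  structure(
    list(nonregional_groups = nonregional_groups,
         regional_groups = regional_groups,
         pops_per_group = as.integer(pops_per_group),
         regional_pops_per_group = as.integer(regional_pops_per_group),
         n_broad_loci = as.integer(n_broad_loci),
         n_regional_loci = as.integer(n_regional_loci),
         n_alleles = as.integer(n_alleles),
         ploidy = as.integer(ploidy),
         baseline_n = as.integer(baseline_n),
         theta_broad = theta_broad,
         theta_regional = theta_regional,
         mixture_size = as.integer(mixture_size),
         true_group_proportions = stats::setNames(true_group_proportions,
                                                  groups),
         confuse = confuse),
    class = "synthetic_scenario"
  )
}

# population registry implied by a scenario
scenario_pops <- function(sc) {
  nonreg <- do.call(rbind, lapply(sc$nonregional_groups, function(g)
    data.frame(pop = paste0(g, "_p", seq_len(sc$pops_per_group)),
               group = g, region = NA_character_)))
  reg <- do.call(rbind, lapply(names(sc$regional_groups), function(r)
    do.call(rbind, lapply(sc$regional_groups[[r]], function(g)
      data.frame(pop = paste0(g, "_p", seq_len(sc$regional_pops_per_group)),
                 group = g, region = r)))))
  rbind(nonreg, reg)
}

#' Region map implied by a synthetic scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [region_map()] linking every synthetic population to its
#'   reporting group and every regional group to its region.
#' @export
scenario_region_map <- function(scenario) {
  pops <- scenario_pops(scenario)
  reg_of <- unlist(lapply(names(scenario$regional_groups), function(r)
    stats::setNames(rep(r, length(scenario$regional_groups[[r]])),
                    scenario$regional_groups[[r]])))
  rg_of <- lapply(stats::setNames(nm = names(scenario$regional_groups)),
                  function(r) {
    sub <- pops[!is.na(pops$region) & pops$region == r, ]
    stats::setNames(sub$group, sub$pop)
  })
  region_map(
    broad_group_of = stats::setNames(pops$group, pops$pop),
    region_of_group = reg_of,
    regional_group_of = rg_of
  )
}

allele_names <- function(n) {
  if (n <= 4) c("A", "C", "G", "T")[seq_len(n)] else
    sprintf("a%02d", seq_len(n))
}

#' Generate one synthetic baseline level
#'
#' Draws, for each locus, an ancestral frequency vector from a flat
#' Dirichlet and, for each population, frequencies
#' `q_k ~ Dirichlet(theta * ancestral)`; individual fish are then drawn
#' allele by allele so that leave-out mixtures can be synthesized later.
#' The broad level covers every population in the scenario; a regional
#' level exposes only the region's populations as baseline but keeps the
#' other populations' genotypes at the regional markers attached (as
#' `$aux_fish`), since mixture fish from outside the region still need
#' regional genotypes.
#'
#' @param scenario A [synthetic_scenario()].
#' @param level `"broad"` or a region id from the scenario.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A `baseline_data` object with extra fields: `fish` (per
#'   population, an n x L x ploidy array of allele indices), `q_true`
#'   (per locus, the latent K x J frequency matrix), and for regional
#'   levels `aux_pops`/`aux_fish` for out-of-region populations.
#' @export
generate_baseline <- function(scenario, level = "broad", seed = NULL) {
  with_seed(seed, {
    sc <- scenario
    pops <- scenario_pops(sc)
    broad_level <- identical(level, "broad")
    if (!broad_level && !level %in% names(sc$regional_groups)) {
      stop("unknown level '", level, "'")
    }
    L <- if (broad_level) sc$n_broad_loci else sc$n_regional_loci
    theta <- if (broad_level) sc$theta_broad else sc$theta_regional
    prefix <- if (broad_level) "bl" else paste0(level, "_l")
    loci <- lapply(seq_len(L), function(l)
      locus_spec(sprintf("%s%02d", prefix, l), allele_names(sc$n_alleles),
                 sc$ploidy))
    Kall <- nrow(pops)
    J <- sc$n_alleles

    # latent frequencies: ancestral per locus, population drift around it
    ancestral <- lapply(seq_len(L), function(l) rdirichlet1(rep(1, J)))
    q_true <- lapply(seq_len(L), function(l)
      rdirichlet(Kall, theta * ancestral[[l]]))
    if (broad_level && !is.null(sc$confuse)) {
      foc <- which(pops$group == sc$confuse$group)
      nr <- which(is.na(pops$region))
      tgt <- nr[(seq_along(foc) - 1L) %% length(nr) + 1L]
      w <- sc$confuse$weight
      for (l in seq_len(L)) {
        q_true[[l]][foc, ] <- (1 - w) * q_true[[l]][foc, , drop = FALSE] +
          w * q_true[[l]][tgt, , drop = FALSE]
      }
    }

    # individual fish, allele by allele
    fish <- lapply(seq_len(Kall), function(k) {
      g <- array(0L, dim = c(sc$baseline_n, L, sc$ploidy))
      for (l in seq_len(L)) {
        g[, l, ] <- sample.int(J, sc$baseline_n * sc$ploidy, replace = TRUE,
                               prob = q_true[[l]][k, ])
      }
      g
    })
    names(fish) <- pops$pop

    keep <- if (broad_level) seq_len(Kall) else
      which(!is.na(pops$region) & pops$region == level)
    base <- baseline_from_fish(loci, pops$pop[keep], fish[keep])
    base$q_true <- lapply(q_true, function(m) m[keep, , drop = FALSE])
    if (!broad_level) {
      base$aux_pops <- pops$pop[-keep]
      base$aux_fish <- fish[-keep]
    }
    class(base) <- c("sim_baseline", class(base))
    base
  })
}

# aggregate individual fish into baseline allele counts
baseline_from_fish <- function(loci, pop_names, fish) {
  K <- length(pop_names)
  L <- length(loci)
  counts <- lapply(seq_len(L), function(l) {
    m <- t(vapply(fish, function(g) {
      tabulate(g[, l, ], nbins = length(loci[[l]]$alleles))
    }, integer(length(loci[[l]]$alleles))))
    matrix(as.integer(m), nrow = K,
           dimnames = list(NULL, loci[[l]]$alleles))
  })
  n <- vapply(fish, function(g) dim(g)[1], integer(1))
  base <- baseline_data(loci, pop_names, counts,
                        matrix(n, K, L))
  base$fish <- fish
  base
}

#' Draw random true reporting-group proportions
#'
#' Flat Dirichlet over the reporting groups, as used for the replicate
#' cross-validation analyses.
#'
#' @param n_groups Number of reporting groups.
#' @param seed Optional seed.
#' @return A simplex vector of length `n_groups`.
#' @export
random_true_proportions <- function(n_groups, seed = NULL) {
  with_seed(seed, rdirichlet1(rep(1, n_groups)))
}

#' Generate all inputs of a synthetic two-stage study
#'
#' Convenience wrapper producing the broad baseline, every regional
#' baseline and the region map from one scenario, with per-level seeds
#' derived from the master seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Master seed.
#' @return `list(scenario, region_map, broad, regional)` where `regional`
#'   is a named list of simulated baselines.
#' @export
simulate_study <- function(scenario, seed = NULL) {
  regions <- names(scenario$regional_groups)
  seeds <- if (is.null(seed)) rep(list(NULL), 1 + length(regions)) else
    as.list(derive_seeds(seed, 1 + length(regions)))
  broad <- generate_baseline(scenario, "broad", seed = seeds[[1]])
  regional <- stats::setNames(lapply(seq_along(regions), function(i)
    generate_baseline(scenario, regions[i], seed = seeds[[i + 1]])),
    regions)
  list(scenario = scenario, region_map = scenario_region_map(scenario),
       broad = broad, regional = regional)
}

#' Synthesize a leave-out mixture at known group proportions
#'
#' Group sizes are `round(p_g * M)` with largest-remainder correction so
#' they sum exactly to `M`; within a group, source populations are chosen
#' uniformly at random among those with fish remaining.  Drawn fish carry
#' genotypes at every baseline's marker set and are removed from every
#' returned baseline in which they occur, so the mixture and the pruned
#' baselines share no fish.
#'
#' @param broad_base Simulated broad baseline from [generate_baseline()].
#' @param regional_bases Named list of simulated regional baselines.
#' @param rm The [region_map()] linking the two levels.
#' @param true_props Named true proportions over the combined reporting
#'   groups (non-regional first, then regional).
#' @param M Mixture size.
#' @param seed Optional seed.
#' @return `list(mix_broad, mix_regional, broad_base, regional_bases,
#'   truth)`: the two-level mixture data, the pruned baselines, and a
#'   truth record with target and realized proportions plus each fish's
#'   source population.
#' @export
synthesize_mixture <- function(broad_base, regional_bases, rm, true_props,
                               M, seed = NULL) {
  with_seed(seed, {
    groups <- combined_group_names(rm)
    if (is.null(names(true_props))) names(true_props) <- groups
    stopifnot(setequal(names(true_props), groups))
    sizes <- largest_remainder(true_props[groups], M)

    region_of_pop <- stats::setNames(
      rep(names(rm$regional_group_of),
          vapply(rm$regional_group_of, length, integer(1))),
      unlist(lapply(rm$regional_group_of, names), use.names = FALSE))

    # candidate populations per combined group
    pops_of_group <- lapply(groups, function(g) {
      if (g %in% nonregional_groups(rm)) {
        p <- names(rm$broad_group_of)[rm$broad_group_of == g]
        setdiff(p, names(region_of_pop))
      } else {
        r <- names(which(vapply(rm$regional_group_of, function(x)
          g %in% x, logical(1))))[1]
        rg <- rm$regional_group_of[[r]]
        names(rg)[rg == g]
      }
    })
    names(pops_of_group) <- groups

    avail <- lapply(broad_base$fish, function(g) seq_len(dim(g)[1]))
    picks <- list()  # per fish: pop
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      for (i in seq_len(sizes[gi])) {
        cand <- pops_of_group[[g]]
        cand <- cand[vapply(cand, function(p) length(avail[[p]]) > 0,
                            logical(1))]
        if (length(cand) == 0L) {
          stop("group '", g, "': requested draws exceed available ",
               "baseline fish")
        }
        p <- cand[sample.int(length(cand), 1)]
        idx <- avail[[p]][sample.int(length(avail[[p]]), 1)]
        avail[[p]] <- setdiff(avail[[p]], idx)
        picks[[length(picks) + 1L]] <- list(pop = p, idx = idx, group = g)
      }
    }

    ids <- sprintf("mix_%03d", seq_along(picks))
    src_pop <- vapply(picks, `[[`, "", "pop")
    src_idx <- vapply(picks, function(x) x$idx, integer(1))
    src_grp <- vapply(picks, `[[`, "", "group")

    mix_broad <- mixture_from_fish(broad_base$loci, ids, lapply(picks,
      function(pk) broad_base$fish[[pk$pop]][pk$idx, , , drop = FALSE]))
    mix_regional <- lapply(regional_bases, function(rb) {
      all_fish <- c(rb$fish, rb$aux_fish)
      mixture_from_fish(rb$loci, ids, lapply(picks,
        function(pk) all_fish[[pk$pop]][pk$idx, , , drop = FALSE]))
    })

    removed <- split(src_idx, src_pop)
    broad_pruned <- prune_baseline(broad_base, removed)
    regional_pruned <- lapply(regional_bases, function(rb)
      prune_baseline(rb, removed[names(removed) %in% rb$populations]))

    truth <- list(
      proportions = stats::setNames(as.numeric(sizes) / M, groups),
      target = true_props[groups],
      sizes = stats::setNames(sizes, groups),
      fish = data.frame(indiv = ids, pop = src_pop, group = src_grp)
    )
    list(mix_broad = mix_broad, mix_regional = mix_regional,
         broad_base = broad_pruned, regional_bases = regional_pruned,
         truth = truth)
  })
}

mixture_from_fish <- function(loci, ids, fish_rows) {
  M <- length(ids)
  counts <- lapply(seq_along(loci), function(l) {
    m <- t(vapply(fish_rows, function(g)
      tabulate(g[1, l, ], nbins = length(loci[[l]]$alleles)),
      integer(length(loci[[l]]$alleles))))
    matrix(as.integer(m), nrow = M,
           dimnames = list(NULL, loci[[l]]$alleles))
  })
  mixture_data(loci, ids, counts)
}

# drop the given fish (list: pop -> indices) and recompute counts
prune_baseline <- function(base, removed) {
  for (p in names(removed)) {
    k <- match(p, base$populations)
    if (is.na(k)) next
    keep <- setdiff(seq_len(dim(base$fish[[k]])[1]), removed[[p]])
    base$fish[[k]] <- base$fish[[k]][keep, , , drop = FALSE]
  }
  out <- baseline_from_fish(base$loci, base$populations, base$fish)
  out$q_true <- base$q_true
  out$aux_pops <- base$aux_pops
  out$aux_fish <- base$aux_fish
  class(out) <- class(base)
  out
}
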