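#' Describe a genetic marker (locus)
#'
#' @param name Locus identifier.
#' @param alleles Character vector of allele names observed at the locus
#'   (unique; stored sorted so repeated loads are bit-identical).
#' @param ploidy Number of copies of the locus carried per individual
#'   (2 for diploid markers).
#' @return A `locus_spec` object.
#' @examples
#' locus_spec("Ots_101", c("A", "G"))
#' @export
locus_spec <- function(name, alleles, ploidy = 2L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  alleles <- as.character(alleles)
  if (length(alleles) < 1L) stop("locus '", name, "': needs at least one allele")
  if (anyDuplicated(alleles)) stop("locus '", name, "': duplicated allele names")
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("locus '", name, "': ploidy must be >= 1")
  structure(
    list(name = name, alleles = sort(alleles), ploidy = ploidy),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus %s: %d alleles, ploidy %d>\n",
              x$name, length(x$alleles), x$ploidy))
  invisible(x)
}

#' Baseline allele counts for known spawning populations
#'
#' The reference data a GSI analysis conditions on: for every population
#' `k`, locus `l` and allele `j`, the allele count `y[k, l, j]` together
#' with the per-population, per-locus number of genotyped fish `n[k, l]`.
#' Counts are stored as one matrix per locus (populations x alleles),
#' because loci carry different numbers of alleles.
#'
#' @param loci List of [locus_spec()] objects.
#' @param populations Character vector of population names (order preserved).
#' @param counts List (one element per locus) of integer matrices with
#'   `length(populations)` rows and one column per allele of that locus.
#' @param sample_sizes Integer matrix, populations x loci, of the number of
#'   fish genotyped (`sum_j counts[k, l, j] == ploidy_l * sample_sizes[k, l]`).
#' @return A `baseline_data` object.
#' @seealso [read_genotypes()], [mixture_data()]
#' @export
baseline_data <- function(loci, populations, counts, sample_sizes) {
  obj <- structure(
    list(loci = loci, populations = as.character(populations),
         counts = counts, sample_sizes = sample_sizes),
    class = "baseline_data"
  )
  validate_baseline(obj)
  obj
}

validate_baseline <- function(x) {
  stopifnot(inherits(x, "baseline_data"))
  K <- length(x$populations)
  L <- length(x$loci)
  if (anyDuplicated(x$populations)) stop("duplicated population names")
  if (length(x$counts) != L) stop("counts must have one element per locus")
  if (!all(dim(x$sample_sizes) == c(K, L))) {
    stop("sample_sizes must be populations x loci")
  }
  for (l in seq_len(L)) {
    sp <- x$loci[[l]]
    m <- x$counts[[l]]
    if (nrow(m) != K || ncol(m) != length(sp$alleles)) {
      stop("counts for locus '", sp$name, "' have wrong dimensions")
    }
    if (any(m < 0) || any(m != round(m))) {
      stop("counts for locus '", sp$name, "' must be non-negative integers")
    }
    ok <- rowSums(m) == sp$ploidy * x$sample_sizes[, l]
    if (!all(ok)) {
      stop("allele counts at locus '", sp$name, "' do not match ploidy * n for ",
           "population(s): ", paste(x$populations[!ok], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.baseline_data <- function(x, ...) {
  cat(sprintf("<baseline: %d populations, %d loci, %d fish>\n",
              length(x$populations), length(x$loci),
              sum(x$sample_sizes[, 1])))
  invisible(x)
}

#' Multilocus genotypes of a mixed-stock sample
#'
#' Unlabelled individuals from a mixture (e.g. a fishery catch): per
#' individual `m`, locus `l` and allele `j` the allele count `x[m, l, j]`,
#' plus a logical mask of which loci were successfully genotyped.
#'
#' @param loci List of [locus_spec()] objects.
#' @param individuals Character vector of fish identifiers.
#' @param counts List (per locus) of integer matrices, individuals x alleles.
#' @param observed Logical matrix, individuals x loci; `FALSE` marks a
#'   missing genotype (that locus contributes nothing to the likelihood).
#' @return A `mixture_data` object.
#' @export
mixture_data <- function(loci, individuals, counts, observed = NULL) {
  M <- length(individuals)
  L <- length(loci)
  if (is.null(observed)) {
    observed <- matrix(TRUE, M, L)
  }
  obj <- structure(
    list(loci = loci, individuals = as.character(individuals),
         counts = counts, observed = observed),
    class = "mixture_data"
  )
  validate_mixture(obj)
  obj
}

validate_mixture <- function(x) {
  stopifnot(inherits(x, "mixture_data"))
  M <- length(x$individuals)
  L <- length(x$loci)
  if (anyDuplicated(x$individuals)) stop("duplicated individual ids")
  if (length(x$counts) != L) stop("counts must have one element per locus")
  if (!all(dim(x$observed) == c(M, L))) stop("observed mask must be individuals x loci")
  for (l in seq_len(L)) {
    sp <- x$loci[[l]]
    m <- x$counts[[l]]
    if (nrow(m) != M || ncol(m) != length(sp$alleles)) {
      stop("counts for locus '", sp$name, "' have wrong dimensions")
    }
    rs <- rowSums(m)
    if (any(rs[x$observed[, l]] != sp$ploidy)) {
      stop("observed genotypes at locus '", sp$name, "' must carry exactly ",
           sp$ploidy, " alleles")
    }
    if (any(rs[!x$observed[, l]] != 0)) {
      stop("missing genotypes at locus '", sp$name, "' must have zero counts")
    }
  }
  invisible(x)
}

#' @export
print.mixture_data <- function(x, ...) {
  cat(sprintf("<mixture: %d individuals, %d loci, %.1f%% loci missing>\n",
              length(x$individuals), length(x$loci),
              100 * mean(!x$observed)))
  invisible(x)
}

#' Link broad-scale populations to reporting groups and sub-regions
#'
#' A region map ties the two stages of a multistage analysis together:
#' every broad-scale population belongs to a broad reporting group; a broad
#' reporting group may be covered by at most one regional baseline
#' (sub-region); and each regional baseline's populations belong to regional
#' reporting groups.  Sub-regions are disjoint: a regional population occurs
#' in exactly one region.
#'
#' @param broad_group_of Named character vector: broad population ->
#'   broad reporting-group name.
#' @param region_of_group Named character vector: broad reporting group ->
#'   region id.  Groups absent from this map (or mapped to `NA`) have no
#'   regional baseline and are reported directly from the broad stage.
#' @param regional_group_of Named list, one element per region id; each
#'   element is a named character vector regional population -> regional
#'   reporting-group name.
#' @return A `region_map` object.
#' @examples
#' region_map(
#'   broad_group_of = c(p1 = "A", p2 = "B", p3 = "C", p4 = "C"),
#'   region_of_group = c(C = "yuk"),
#'   regional_group_of = list(yuk = c(r1 = "Ca", r2 = "Cb"))
#' )
#' @export
region_map <- function(broad_group_of, region_of_group = character(),
                       regional_group_of = list()) {
  region_of_group <- region_of_group[!is.na(region_of_group)]
  obj <- structure(
    list(broad_group_of = broad_group_of,
         region_of_group = region_of_group,
         regional_group_of = regional_group_of),
    class = "region_map"
  )
  validate_region_map(obj)
  obj
}

validate_region_map <- function(x) {
  stopifnot(inherits(x, "region_map"))
  if (is.null(names(x$broad_group_of)) || anyDuplicated(names(x$broad_group_of))) {
    stop("broad_group_of must be uniquely named by population")
  }
  groups <- unique(unname(x$broad_group_of))
  unknown <- setdiff(names(x$region_of_group), groups)
  if (length(unknown)) {
    stop("region assigned to unknown broad group(s): ",
         paste(unknown, collapse = ", "))
  }
  regions <- unique(unname(x$region_of_group))
  missing_reg <- setdiff(regions, names(x$regional_group_of))
  empty <- regions[vapply(regions, function(r)
    length(x$regional_group_of[[r]] %||% character()) == 0L, logical(1))]
  if (length(missing_reg) || length(empty)) {
    stop("region(s) with no regional populations: ",
         paste(union(missing_reg, empty), collapse = ", "))
  }
  orphan <- setdiff(names(x$regional_group_of), regions)
  if (length(orphan)) {
    stop("regional baseline(s) whose region id is not assigned to any broad ",
         "group: ", paste(orphan, collapse = ", "))
  }
  pops <- unlist(lapply(x$regional_group_of, names), use.names = FALSE)
  if (anyDuplicated(pops)) {
    stop("population(s) occur in more than one region: ",
         paste(unique(pops[duplicated(pops)]), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region map: %d broad pops, %d broad groups, %d region(s)>\n",
              length(x$broad_group_of),
              length(unique(x$broad_group_of)),
              length(x$regional_group_of)))
  invisible(x)
}

# ---- region-map helpers -----------------------------------------------------

region_ids <- function(rm) names(rm$regional_group_of)

# broad groups with no regional baseline, in order of first appearance
nonregional_groups <- function(rm) {
  g <- unique(unname(rm$broad_group_of))
  setdiff(g, names(rm$region_of_group))
}

# broad groups mapped to region r
groups_in_region <- function(rm, r) {
  names(rm$region_of_group)[rm$region_of_group == r]
}

# names of the combined reporting-group vector: non-regional broad groups
# first, then each region's regional groups
combined_group_names <- function(rm) {
  c(nonregional_groups(rm),
    unlist(lapply(region_ids(rm), function(r)
      unique(unname(rm$regional_group_of[[r]]))), use.names = FALSE))
}

#' Prior settings for a GSI run
#'
#' @param alpha_mode How the Dirichlet prior on mixture proportions spreads
#'   its unit total weight: `"per_group_flat"` (equal weight per reporting
#'   group, split equally among the group's populations; the default) or
#'   `"per_population_flat"` (`1/K` per population).
#' @param beta Optional per-locus allele-frequency prior weights; the default
#'   `NULL` uses `1/J_l` for each of a locus's `J_l` alleles.
#' @param alpha Optional explicit per-population proportion prior weights,
#'   overriding `alpha_mode`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(alpha_mode = c("per_group_flat", "per_population_flat"),
                       beta = NULL, alpha = NULL) {
  alpha_mode <- match.arg(alpha_mode)
  if (!is.null(alpha) && any(alpha <= 0)) stop("alpha weights must be positive")
  if (!is.null(beta) && any(unlist(beta) <= 0)) stop("beta weights must be positive")
  structure(list(alpha_mode = alpha_mode, beta = beta, alpha = alpha),
            class = "prior_spec")
}

#' MCMC settings
#'
#' Defaults follow the standard production schedule for this sampler family:
#' five independent chains of 25,000 iterations, the first 15,000 discarded
#' as burn-in and the remainder thinned to every fifth draw, giving 10,000
#' retained draws in total.
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded per chain (must be < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Master random seed; per-chain streams are derived from it.
#' @param model `"conditional"` (baseline allele frequencies integrated out;
#'   the default) or `"fully_bayesian"` (frequencies updated by Gibbs).
#' @param record_memberships Keep per-iteration individual membership draws
#'   (memory-hungry; needed only for assignment-probability reporting, which
#'   is otherwise available from accumulated counts).
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(n_chains = 5L, n_iter = 25000L, n_burn = 15000L,
                        thin = 5L, seed = NULL,
                        model = c("conditional", "fully_bayesian"),
                        record_memberships = FALSE) {
  model <- match.arg(model)
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burn <- as.integer(n_burn); thin <- as.integer(thin)
  stopifnot(n_chains >= 1L, n_iter >= 1L, n_burn >= 0L, thin >= 1L)
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  structure(
    list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn, thin = thin,
         seed = seed, model = model, record_memberships = record_memberships),
    class = "mcmc_config"
  )
}

#' Number of retained posterior draws under a schedule
#'
#' @param config An [mcmc_config()].
#' @param per_chain If `TRUE`, draws per chain rather than the total.
#' @return Integer count of retained (post-burn-in, thinned) draws.
#' @examples
#' retained_draws(mcmc_config())  # 5 * (25000 - 15000) / 5 = 10000
#' @export
retained_draws <- function(config, per_chain = FALSE) {
  per <- (config$n_iter - config$n_burn) %/% config$thin
  if (per_chain) per else per * config$n_chains
}
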