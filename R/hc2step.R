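# The conventional "hard cut-off" two-step procedure: an independent
# broad-scale GSI, threshold selection of individuals, then an independent
# regional GSI on the selected fish.  Because the stages are separate, the
# regional intervals do not carry the first stage's assignment uncertainty -
# the defect the integrated multistage sampler removes.

#' Individual assignment probabilities from broad-scale draws
#'
#' The posterior probability that each fish belongs to each broad
#' reporting group: the fraction of retained draws in which the fish's
#' membership fell in the group's populations.
#'
#' @param draws A [gsi_draws] object from a broad-scale [run_single_gsi()].
#' @param rm The [region_map()] defining which broad groups form each
#'   region; defaults to the map stored in `draws` (which has no regions
#'   when the draws come from a plain single-baseline run).
#' @return An `assignment_table`: list with `probs` (fish x broad groups),
#'   `region_probs` (fish x regions, group probabilities summed within each
#'   region), and the draw total used.
#' @export
assignment_probabilities <- function(draws, rm = draws$region_map) {
  total <- sum(draws$z_hits[1, ])
  G <- outer(unname(rm$broad_group_of[draws$broad_pops]),
             draws$broad_groups, `==`) + 0
  probs <- draws$z_hits %*% G / total
  dimnames(probs) <- list(draws$individuals, draws$broad_groups)
  regions <- region_ids(rm)
  region_probs <- vapply(regions, function(r)
    rowSums(probs[, groups_in_region(rm, r), drop = FALSE]),
    numeric(nrow(probs)))
  region_probs <- matrix(region_probs, nrow = nrow(probs),
                         dimnames = list(draws$individuals, regions))
  structure(list(probs = probs, region_probs = region_probs, total = total),
            class = "assignment_table")
}

#' Select fish for the second step
#'
#' Fish whose probability of belonging to the region exceeds the threshold
#' strictly (`prob > tau`); a fish at exactly `tau` is excluded.
#'
#' @param table An `assignment_table`.
#' @param region Region id.
#' @param tau Probability threshold (default 0.8).
#' @return Integer indices of the selected fish.
#' @export
select_for_stage2 <- function(table, region, tau = 0.8) {
  unname(which(table$region_probs[, region] > tau))
}

#' Hard cut-off two-step GSI
#'
#' Stage 1 runs [run_single_gsi()] on the broad baseline; per region, fish
#' assigned to the region with probability above `tau` are selected and
#' stage 2 runs [run_single_gsi()] on the regional baseline restricted to
#' them.  The combined report keeps non-regional broad groups at their
#' stage-1 posterior and rescales each region's stage-2 draws by a fixed
#' constant: the stage-1 posterior *mean* of the region's total proportion
#' (default), or the selected-fish fraction
#' (`rescale = "selected_fraction"`).  Either way the constant carries no
#' uncertainty, so regional credible intervals ignore stage-1 error -
#' deliberately reproducing the method's known deficiency.
#'
#' @inheritParams run_msgsi
#' @param tau Stage-2 selection threshold.
#' @param rescale How stage-2 draws are scaled into combined proportions.
#' @return A [gsi_draws] object (combined draws) with extra fields
#'   `assignment` (the stage-1 [assignment_probabilities()] table),
#'   `selected` and `scale` per region, and the `stage1` draws.
#' @export
run_hc2step <- function(mix_broad, mix_regional = list(), broad_base,
                        regional_bases = list(), region_map,
                        prior = prior_spec(), mcmc = mcmc_config(),
                        tau = 0.8,
                        rescale = c("stage1_mean", "selected_fraction")) {
  rescale <- match.arg(rescale)
  rm <- region_map
  validate_region_map(rm)
  regions <- region_ids(rm)
  seed <- mcmc$seed %||% sample.int(2147483646L, 1)
  stage_seeds <- derive_seeds(seed, 1 + length(regions))

  mcmc1 <- mcmc; mcmc1$seed <- stage_seeds[1]
  stage1 <- run_single_gsi(mix_broad, broad_base, rm$broad_group_of,
                           prior, mcmc1)
  at <- assignment_probabilities(stage1, rm)

  n_keep <- retained_draws(mcmc, per_chain = TRUE)
  combined <- lapply(stage1$combined, function(m)
    m[, nonregional_groups(rm), drop = FALSE])
  selected <- list(); scale <- list(); stage2 <- list()

  for (i in seq_along(regions)) {
    r <- regions[i]
    sel <- select_for_stage2(at, r, tau)
    selected[[r]] <- sel
    s_r <- if (rescale == "stage1_mean") {
      mean(vapply(stage1$broad_group, function(m)
        mean(rowSums(m[, groups_in_region(rm, r), drop = FALSE])),
        numeric(1)))
    } else {
      length(sel) / length(mix_broad$individuals)
    }
    scale[[r]] <- s_r
    rg <- rm$regional_group_of[[r]]
    gnames <- unique(unname(rg))
    mcmc_r <- mcmc; mcmc_r$seed <- stage_seeds[1 + i]
    if (length(sel) == 0L) {
      warning("region '", r, "': no fish passed the ", tau,
              " threshold; regional groups reported from the prior only")
      alpha_r <- build_alpha(names(rg), rg, prior)
      Gr <- outer(unname(rg[names(rg)]), gnames, `==`) + 0
      reg_draws <- with_seed(stage_seeds[1 + i], lapply(
        seq_len(mcmc$n_chains), function(ci) {
          m <- rdirichlet(n_keep, alpha_r) %*% Gr
          colnames(m) <- gnames
          m
        }))
    } else {
      fit <- run_single_gsi(subset_mix_rows(mix_regional[[r]],
                                            seq_along(mix_broad$individuals)
                                            %in% sel),
                            regional_bases[[r]], rg, prior, mcmc_r)
      stage2[[r]] <- fit
      reg_draws <- lapply(fit$combined, function(m)
        m[, gnames, drop = FALSE])
    }
    for (ci in seq_along(combined)) {
      combined[[ci]] <- cbind(combined[[ci]], reg_draws[[ci]] * s_r)
    }
  }

  out <- stage1
  out$group_names <- combined_group_names(rm)
  out$combined <- lapply(combined, function(m)
    m[, out$group_names, drop = FALSE])
  out$region_map <- rm
  out$assignment <- at
  out$selected <- selected
  out$scale <- scale
  out$stage1 <- stage1
  out$stage2 <- stage2
  out
}
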