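# Genotype files are wide CSVs in the common GSI-lab export shape: one row
# per fish, ploidy_l columns per locus named `<locus>`, `<locus>.1`, ...
# holding allele names, blank for missing.  Baseline files carry a `pop`
# column, mixture files an `indiv` column.

#' Read a wide genotype CSV
#'
#' Parses a genotype table into a [baseline_data()] (allele counts
#' aggregated per population) or a [mixture_data()] (per-individual counts
#' with a missing-locus mask).  The allele registry of each locus is the
#' sorted union of the alleles seen in the file, so repeated loads are
#' bit-identical.  A fully blank locus reduces the per-locus sample size
#' `n[k, l]` (baseline) or sets `observed = FALSE` (mixture); a genotype
#' with some but not all allele cells filled is a hard error naming the row
#' and locus.
#'
#' @param path CSV file path.
#' @param role `"baseline"` or `"mixture"`.
#' @return A `baseline_data` or `mixture_data` object.
#' @seealso [write_genotypes()], [align_mixture_to_baseline()]
#' @export
read_genotypes <- function(path, role = c("baseline", "mixture")) {
  role <- match.arg(role)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character())
  id_col <- if (role == "baseline") "pop" else "indiv"
  if (!id_col %in% names(df)) {
    stop("genotype file '", path, "' lacks required column '", id_col, "'")
  }
  ids <- df[[id_col]]
  geno_cols <- setdiff(names(df), id_col)
  base_names <- sub("\\.[0-9]+$", "", geno_cols)
  locus_names <- unique(base_names)
  if (role == "mixture" && anyDuplicated(ids)) {
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n_row <- nrow(df)

  loci <- vector("list", length(locus_names))
  counts <- vector("list", length(locus_names))
  observed <- matrix(TRUE, n_row, length(locus_names))
  for (l in seq_along(locus_names)) {
    cols <- geno_cols[base_names == locus_names[l]]
    cells <- as.matrix(df[, cols, drop = FALSE])
    blank <- !nzchar(cells) | is.na(cells)
    n_blank <- rowSums(blank)
    ragged <- n_blank > 0 & n_blank < length(cols)
    if (any(ragged)) {
      stop("row ", which(ragged)[1], " (", ids[which(ragged)[1]],
           "): incomplete genotype at locus '", locus_names[l],
           "' (fill all ", length(cols), " allele cells or none)")
    }
    alleles <- sort(unique(cells[!blank]))
    if (length(alleles) == 0L) alleles <- "?"  # locus never observed
    loci[[l]] <- locus_spec(locus_names[l], alleles, ploidy = length(cols))
    cnt <- matrix(0L, n_row, length(alleles),
                  dimnames = list(NULL, alleles))
    for (cc in seq_along(cols)) {
      seen <- !blank[, cc]
      if (any(seen)) {
        idx <- cbind(which(seen), match(cells[seen, cc], alleles))
        # genotypes can repeat an allele, so accumulate
        for (i in seq_len(nrow(idx))) {
          cnt[idx[i, 1], idx[i, 2]] <- cnt[idx[i, 1], idx[i, 2]] + 1L
        }
      }
    }
    counts[[l]] <- cnt
    observed[, l] <- n_blank == 0L
  }

  if (role == "mixture") {
    return(mixture_data(loci, ids, counts, observed))
  }
  pops <- unique(ids)  # file order of first appearance
  K <- length(pops)
  pop_idx <- match(ids, pops)
  agg <- lapply(counts, function(m) {
    out <- rowsum(m, pop_idx)
    storage.mode(out) <- "integer"
    rownames(out) <- NULL
    out
  })
  n_kl <- vapply(seq_along(loci), function(l) {
    as.integer(rowsum(as.integer(observed[, l]), pop_idx))
  }, integer(K))
  n_kl <- matrix(n_kl, nrow = K)
  baseline_data(loci, pops, agg, n_kl)
}

#' Write genotypes back to the wide CSV dialect
#'
#' Inverse of [read_genotypes()] up to allele ordering within a genotype:
#' alleles are written in registry (sorted) order, so
#' `read(write(read(x)))` equals `read(x)`.  Baselines can only be written
#' from simulated objects that still carry individual fish
#' (see [generate_baseline()]); aggregated counts cannot be disaggregated.
#'
#' @param x A `mixture_data`, or a simulated baseline with fish attached.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  if (inherits(x, "mixture_data")) {
    df <- genotype_frame(x$counts, x$loci, x$observed)
    df <- cbind(indiv = x$individuals, df)
  } else if (inherits(x, "baseline_data") && !is.null(x$fish)) {
    rows <- fish_genotype_frame(x)
    df <- rows
  } else {
    stop("cannot write per-fish genotypes from aggregated baseline counts")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# expand count matrices into allele-name cells, registry order
genotype_frame <- function(counts, loci, observed) {
  out <- list()
  for (l in seq_along(loci)) {
    sp <- loci[[l]]
    cells <- matrix("", nrow(counts[[l]]), sp$ploidy)
    for (m in which(observed[, l])) {
      cells[m, ] <- rep(sp$alleles, counts[[l]][m, ])
    }
    cols <- if (sp$ploidy == 1L) sp$name else
      c(sp$name, paste0(sp$name, ".", seq_len(sp$ploidy - 1L)))
    colnames(cells) <- cols
    out[[l]] <- cells
  }
  as.data.frame(do.call(cbind, out), check.names = FALSE)
}

fish_genotype_frame <- function(base) {
  blocks <- lapply(seq_along(base$populations), function(k) {
    g <- base$fish[[k]]  # n x L x ploidy allele indices
    n <- dim(g)[1]
    if (n == 0L) return(NULL)
    cells <- lapply(seq_along(base$loci), function(l) {
      sp <- base$loci[[l]]
      m <- matrix(sp$alleles[g[, l, ]], nrow = n)
      # write each fish's alleles in sorted order for a canonical file
      m <- t(apply(m, 1, sort))
      colnames(m) <- if (sp$ploidy == 1L) sp$name else
        c(sp$name, paste0(sp$name, ".", seq_len(sp$ploidy - 1L)))
      m
    })
    data.frame(pop = base$populations[k], do.call(cbind, cells),
               check.names = FALSE)
  })
  do.call(rbind, blocks)
}

#' Reconcile a mixture's allele registry with a baseline's
#'
#' Reindexes every mixture locus onto the baseline's allele registry so the
#' two share axes.  Every baseline locus must be present in the mixture.
#' Mixture alleles unknown to the baseline are a hard error by default
#' (they would silently zero out an individual's likelihood); with
#' `unknown_alleles = "extend"` the baseline registry gains a zero-count
#' allele column that carries only prior mass.
#'
#' @param mix A [mixture_data()].
#' @param base A [baseline_data()].
#' @param unknown_alleles `"error"` or `"extend"`.
#' @return `list(mixture =, baseline =)` with matching registries, loci in
#'   baseline order.
#' @export
align_mixture_to_baseline <- function(mix, base,
                                      unknown_alleles = c("error", "extend")) {
  unknown_alleles <- match.arg(unknown_alleles)
  mix_names <- vapply(mix$loci, `[[`, "", "name")
  base_names <- vapply(base$loci, `[[`, "", "name")
  missing <- setdiff(base_names, mix_names)
  if (length(missing)) {
    stop("baseline locus(-i) missing from mixture: ",
         paste(missing, collapse = ", "))
  }
  loci <- base$loci
  b_counts <- base$counts
  m_counts <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    sp <- loci[[l]]
    ml <- match(sp$name, mix_names)
    msp <- mix$loci[[ml]]
    if (msp$ploidy != sp$ploidy) {
      stop("locus '", sp$name, "': ploidy differs between mixture and baseline")
    }
    extra <- setdiff(msp$alleles, sp$alleles)
    extra <- extra[colSums(mix$counts[[ml]][, match(extra, msp$alleles),
                                            drop = FALSE]) > 0]
    if (length(extra)) {
      if (unknown_alleles == "error") {
        stop("locus '", sp$name, "': mixture allele(s) absent from baseline: ",
             paste(extra, collapse = ", "))
      }
      old_alleles <- sp$alleles
      sp <- locus_spec(sp$name, c(sp$alleles, extra), sp$ploidy)
      grown <- matrix(0L, length(base$populations), length(sp$alleles),
                      dimnames = list(NULL, sp$alleles))
      grown[, match(old_alleles, sp$alleles)] <- b_counts[[l]]
      b_counts[[l]] <- grown
      loci[[l]] <- sp
    }
    m <- matrix(0L, length(mix$individuals), length(sp$alleles),
                dimnames = list(NULL, sp$alleles))
    shared <- intersect(msp$alleles, sp$alleles)
    m[, shared] <- mix$counts[[ml]][, match(shared, msp$alleles), drop = FALSE]
    m_counts[[l]] <- m
  }
  obs <- mix$observed[, match(base_names, mix_names), drop = FALSE]
  list(
    mixture = mixture_data(loci, mix$individuals, m_counts, obs),
    baseline = baseline_data(loci, base$populations, b_counts,
                             base$sample_sizes)
  )
}

#' Read / write a region map as YAML
#'
#' The file has three blocks: `broad_groups:` (population -> broad group),
#' `regions:` (broad group -> region id), and `regional_groups:` (per
#' region, regional population -> regional group).
#'
#' @param path YAML file path.
#' @return [read_region_map()]: a `region_map`; `write_region_map()`:
#'   `path` invisibly.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  region_map(
    broad_group_of = unlist(y$broad_groups %||% list()),
    region_of_group = unlist(y$regions %||% list()) %||% character(),
    regional_group_of = lapply(y$regional_groups %||% list(), unlist)
  )
}

#' @rdname read_region_map
#' @param rm A `region_map` object.
#' @export
write_region_map <- function(rm, path) {
  yaml::write_yaml(
    list(broad_groups = as.list(rm$broad_group_of),
         regions = as.list(rm$region_of_group),
         regional_groups = lapply(rm$regional_group_of, as.list)),
    path
  )
  invisible(path)
}

#' Write a posterior summary table as TSV
#'
#' Columns mirror the standard GSI report: group, (optional) true
#' proportion, posterior mean, SD, lower/upper 90% credible bound, Rhat and
#' effective size.
#'
#' @param summary A data frame as returned by [summary.gsi_draws()].
#' @param path Output TSV path.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read posterior draws as a flat CSV
#'
#' One row per (chain, retained iteration, reporting group) with the
#' combined group-proportion value.
#'
#' @param draws A [gsi_draws] object (or the data frame from
#'   [as.data.frame.gsi_draws()]).
#' @param path CSV path.
#' @export
write_draws <- function(draws, path) {
  df <- if (is.data.frame(draws)) draws else as.data.frame(draws)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(chain = "integer",
                                       iteration = "integer",
                                       group = "character",
                                       value = "numeric"))
  df
}
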