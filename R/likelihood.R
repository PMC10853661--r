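#' Compound Dirichlet-multinomial probability of a genotype
#'
#' Probability mass of allele counts `x` (summing to the locus ploidy)
#' under a multinomial whose frequency vector has been integrated out
#' against a Dirichlet with weight vector `v`.  This is the genotype
#' likelihood used by the conditional GSI model with `v = beta + y`, i.e.
#' the posterior-predictive weight of baseline population counts `y` under
#' prior `beta`; the baseline frequencies themselves are never updated.
#'
#' @param x Non-negative integer allele counts.
#' @param v Positive Dirichlet weights, same length as `x`.
#' @param log Return the log probability?
#' @return The (log) pmf value, including the multinomial coefficient.
#' @examples
#' # flat weights on a diallelic diploid locus: all 3 genotypes equally likely
#' sapply(list(c(2, 0), c(1, 1), c(0, 2)), dcdm, v = c(1, 1))
#' @export
dcdm <- function(x, v, log = FALSE) {
  stopifnot(length(x) == length(v), all(x >= 0), all(v > 0))
  n <- sum(x)
  lp <- lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(sum(v)) - lgamma(sum(v) + n) +
    sum(lgamma(v + x) - lgamma(v))
  if (log) lp else exp(lp)
}

# default allele-frequency prior: 1/J_l per allele
default_beta <- function(loci) {
  lapply(loci, function(sp) rep(1 / length(sp$alleles), length(sp$alleles)))
}

# resolve a prior_spec's beta against a locus list
resolve_beta <- function(prior, loci) {
  b <- prior$beta %||% default_beta(loci)
  stopifnot(length(b) == length(loci))
  b
}

#' Per-individual, per-population log genotype likelihoods
#'
#' Builds the M x K table of log weights `log P(x_m | population k)` that
#' drives membership sampling.  Unobserved loci contribute zero, and the
#' multinomial coefficient is dropped (it is constant in `k` and cancels
#' when the weights are normalized).
#'
#' For the conditional model (`q = NULL`) the compound
#' Dirichlet-multinomial form with weights `v = beta + y` is used; it is
#' computed once per run because `v` never changes.  For the fully Bayesian
#' model pass the current frequency draw `q` (a per-locus list of K x J
#' matrices) and the table is `sum_l sum_j x_mlj * log(q_klj)`.
#'
#' @param mix A [mixture_data()] aligned to the baseline registry.
#' @param base A [baseline_data()] (conditional model), or `NULL`.
#' @param q Per-locus list of population allele-frequency matrices
#'   (fully Bayesian model), or `NULL`.
#' @param beta Per-locus allele prior weights; default `1/J_l`.
#' @return Matrix of log weights, individuals x populations.  Entries can
#'   be `-Inf` when a frequency is exactly zero where a count is positive.
#' @export
log_genotype_likelihood <- function(mix, base = NULL, q = NULL, beta = NULL) {
  if (is.null(q)) {
    stopifnot(!is.null(base))
    loglik_table_cdm(mix, base, beta %||% default_beta(base$loci))
  } else {
    loglik_table_q(mix, q)
  }
}

# conditional-model table: log CDM up to the multinomial coefficient
loglik_table_cdm <- function(mix, base, beta) {
  M <- length(mix$individuals)
  K <- length(base$populations)
  out <- matrix(0, M, K, dimnames = list(mix$individuals, base$populations))
  for (l in seq_along(base$loci)) {
    sp <- base$loci[[l]]
    v <- base$counts[[l]] + matrix(beta[[l]], K, length(sp$alleles),
                                   byrow = TRUE)
    X <- mix$counts[[l]]
    # sum_j [lgamma(v + x) - lgamma(v)] = sum_j sum_{i=0}^{x-1} log(v + i)
    A <- matrix(0, M, K)
    for (i in 0:(sp$ploidy - 1L)) {
      ind <- X > i
      if (!any(ind)) break
      A <- A + (ind + 0) %*% t(log(v + i))
    }
    const <- lgamma(rowSums(v)) - lgamma(rowSums(v) + sp$ploidy)
    out <- out + A + outer(as.numeric(mix$observed[, l]), const)
  }
  out
}

# fully-Bayesian table for a given frequency state
loglik_table_q <- function(mix, q) {
  M <- nrow(mix$counts[[1]])
  K <- nrow(q[[1]])
  out <- matrix(0, M, K)
  for (l in seq_along(q)) {
    # log(0) is clamped to a huge finite penalty so that 0 * log(0)
    # contributes 0 in the matrix product; any individual that actually
    # carries such an allele is pushed below -1e9 and mapped back to -Inf
    lq <- pmax(log(q[[l]]), -1e10)
    out <- out + mix$counts[[l]] %*% t(lq)
  }
  out[out < -1e9] <- -Inf
  out
}
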