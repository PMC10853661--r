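#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split, non-rank-normalized) PSRF from the between- and
#' within-chain variances of retained draws:
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)` with `B` the
#' between-chain and `W` the mean within-chain variance.  Values close to
#' 1 indicate the chains have mixed.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains), or a
#'   list of equal-length numeric vectors.
#' @param split If `TRUE`, each chain is first split in half (detects
#'   within-chain trends as well).
#' @return The PSRF (>= 1 up to rounding; `NaN` for constant chains).
#' @export
gelman_rubin <- function(x, split = FALSE) {
  x <- as_chain_matrix(x)
  if (split) x <- split_chains(x)
  if (ncol(x) < 2L) stop("at least two chains are required")
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  v_plus <- (n - 1) / n * W + B / n
  if (W == 0) return(if (B == 0) 1 else Inf)
  # values below 1 are estimator noise (e.g. B = 0 for identical chains)
  max(1, sqrt(v_plus / W))
}

#' Effective number of independent draws
#'
#' Multi-chain autocorrelation-based effective sample size: combined
#' autocorrelations are estimated from the within-chain autocovariances
#' relative to the pooled variance, summed with Geyer's initial
#' positive-sequence truncation, and the result is capped at the total
#' number of retained draws.
#'
#' @param x Matrix of draws, iterations x chains, or a list of chains.
#' @return Effective size (`NaN`, with a warning, for constant draws).
#' @export
effective_size <- function(x) {
  x <- as_chain_matrix(x)
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  B <- if (m > 1) n * stats::var(colMeans(x)) else 0
  v_plus <- (n - 1) / n * W + B / n
  if (!is.finite(v_plus) || v_plus == 0) {
    warning("draws are constant; effective size is undefined")
    return(NaN)
  }
  # chain-averaged autocovariances (biased, 1/n normalization)
  lag_max <- n - 1L
  acov <- rowMeans(vapply(seq_len(m), function(j) {
    drop(stats::acf(x[, j], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  }, numeric(lag_max + 1L)))
  rho <- 1 - (W - acov) / v_plus  # rho[1] is lag 0
  # Geyer initial positive monotone sequence over lag pairs
  # (rho_0 + rho_1), (rho_2 + rho_3), ...: stop at the first non-positive
  # pair and never let a pair exceed its predecessor
  pairs <- numeric(0)
  k <- 0L
  repeat {
    i <- 2L * k + 1L
    if (i > length(rho)) break
    val <- rho[i] + (if (i + 1L <= length(rho)) rho[i + 1L] else 0)
    if (!is.finite(val) || (k > 0L && val <= 0)) break
    if (k > 0L) val <- min(val, pairs[k])
    pairs <- c(pairs, val)
    k <- k + 1L
  }
  tau <- -1 + 2 * sum(pairs)
  min(m * n / max(tau, 1e-12), m * n)
}

as_chain_matrix <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  x
}

split_chains <- function(x) {
  n <- nrow(x) %/% 2L
  cbind(x[seq_len(n), , drop = FALSE],
        x[seq_len(n) + (nrow(x) - n), , drop = FALSE])
}

#' Summarize posterior draws of reporting-group proportions
#'
#' Per reporting group: posterior mean, SD, equal-tailed 90% credible
#' interval (5th/95th percentiles, linear interpolation between order
#' statistics - R's default quantile type 7), Gelman-Rubin Rhat and
#' effective size.
#'
#' @param object A [gsi_draws] object.
#' @param truth Optional named vector of true proportions to include as a
#'   `true` column.
#' @param ... Unused.
#' @return A data frame, one row per reporting group.
#' @export
summary.gsi_draws <- function(object, truth = NULL, ...) {
  per_group <- lapply(seq_along(object$group_names), function(g) {
    chains <- vapply(object$combined, function(m) m[, g],
                     numeric(nrow(object$combined[[1]])))
    chains <- matrix(chains, nrow = nrow(object$combined[[1]]))
    pooled <- as.vector(chains)
    data.frame(
      group = object$group_names[g],
      mean = mean(pooled),
      sd = stats::sd(pooled),
      lower_90 = unname(stats::quantile(pooled, 0.05, type = 7)),
      upper_90 = unname(stats::quantile(pooled, 0.95, type = 7)),
      rhat = if (ncol(chains) >= 2) gelman_rubin(chains) else NA_real_,
      n_eff = effective_size(chains)
    )
  })
  out <- do.call(rbind, per_group)
  if (!is.null(truth)) {
    out <- cbind(out[, "group", drop = FALSE],
                 true = unname(truth[out$group]),
                 out[, setdiff(names(out), "group")])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.gsi_draws <- function(x, ...) {
  cat(sprintf("<gsi_draws: %d groups, %d chains x %d retained draws>\n",
              length(x$group_names), length(x$combined),
              nrow(x$combined[[1]])))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Flatten posterior draws to a long data frame
#'
#' @param x A [gsi_draws] object.
#' @param ... Unused.
#' @return Data frame with columns `chain`, `iteration`, `group`, `value`
#'   (combined reporting-group proportions).
#' @export
as.data.frame.gsi_draws <- function(x, ...) {
  T_keep <- nrow(x$combined[[1]])
  do.call(rbind, lapply(seq_along(x$combined), function(ci) {
    m <- x$combined[[ci]]
    data.frame(
      chain = rep(ci, T_keep * ncol(m)),
      iteration = rep(seq_len(T_keep), times = ncol(m)),
      group = rep(colnames(m), each = T_keep),
      value = as.vector(m)
    )
  }))
}

#' Posterior mean reporting-group proportions
#'
#' @param draws A [gsi_draws] object.
#' @return Named vector of posterior means over all chains.
#' @export
posterior_means <- function(draws) {
  s <- Reduce(`+`, lapply(draws$combined, colMeans)) / length(draws$combined)
  stats::setNames(as.numeric(s), draws$group_names)
}

# ---- evaluation metrics -----------------------------------------------------

#' Accuracy metrics for repeated cross-validation estimates
#'
#' For one reporting group across `n` replicate analyses with true
#' proportions `truths` and posterior-mean estimates `estimates`:
#' * `rmse()`: `sqrt(mean((truths - estimates)^2))`;
#' * `bias()`: `mean(estimates) - mean(truths)`;
#' * `pct_deviation()`: percentage of replicates with
#'   `|estimate - truth| > tol` (strictly; an error of exactly `tol` does
#'   not count as a deviation).
#'
#' @param truths,estimates Numeric vectors of equal length.
#' @param tol Deviation tolerance (default 0.1).
#' @return A single number (`pct_deviation` in percent, 0-100).
#' @export
rmse <- function(truths, estimates) {
  stopifnot(length(truths) == length(estimates))
  sqrt(mean((truths - estimates)^2))
}

#' @rdname rmse
#' @export
bias <- function(truths, estimates) {
  stopifnot(length(truths) == length(estimates))
  mean(estimates) - mean(truths)
}

#' @rdname rmse
#' @export
pct_deviation <- function(truths, estimates, tol = 0.1) {
  stopifnot(length(truths) == length(estimates))
  100 * mean(abs(estimates - truths) > tol)
}
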