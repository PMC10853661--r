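#' Draw from a Dirichlet distribution
#'
#' Random draws from a Dirichlet distribution via normalized gamma variates.
#'
#' @param n Number of draws.
#' @param alpha Positive concentration vector.
#' @return A matrix with `n` rows, one simplex draw per row.
#' @examples
#' rdirichlet(3, c(1, 1, 1))
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0), n >= 0)
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(g)
  # all-zero rows can occur for very small shapes; put full mass on the
  # heaviest component rather than returning NaN
  bad <- s == 0
  if (any(bad)) {
    g[bad, which.max(alpha)] <- 1
    s[bad] <- 1
  }
  g / s
}

# single Dirichlet draw as a plain vector
rdirichlet1 <- function(alpha) {
  drop(rdirichlet(1L, alpha))
}

#' Allocate integer counts to groups by largest remainder
#'
#' Converts target proportions into integer group sizes that sum exactly to
#' `total`: each group gets `floor(p * total)` and the leftover units go to
#' the groups with the largest fractional remainders.
#'
#' @param props Non-negative proportions (normalized internally).
#' @param total Positive integer total.
#' @return Integer vector of the same length as `props`, summing to `total`.
#' @examples
#' largest_remainder(c(0.27, 0.10, 0.19, 0.13, 0.31), 205)
#' @export
largest_remainder <- function(props, total) {
  stopifnot(all(props >= 0), sum(props) > 0, total >= 0)
  p <- props / sum(props)
  raw <- p * total
  base <- floor(raw)
  left <- round(total - sum(base))
  if (left > 0) {
    extra <- utils::head(order(raw - base, decreasing = TRUE), left)
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Per-chain seeds derived from a master seed.  Drawing the seeds
# sequentially from a generator seeded with the master value means chain i's
# seed never changes when more chains are added.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(2147483646L, n)
}

# run expr with the RNG seeded (or with the inherited stream if seed NULL)
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(seed %% .Machine$integer.max)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
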