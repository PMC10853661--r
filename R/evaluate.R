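#' Repeated cross-validation evaluation of GSI methods
#'
#' Generates one synthetic study, then for each replicate draws a fresh
#' random truth (flat Dirichlet over reporting groups), synthesizes a
#' leave-out mixture at that truth, and fits the requested methods on the
#' *same* replicate data (a paired design, so method differences are not
#' confounded by simulation noise).  Posterior means are compared to the
#' realized true proportions and aggregated per group into RMSE, bias and
#' percent deviation (share of replicates off by more than 0.1), together
#' with flags against the standard baseline-adequacy guidelines: estimates
#' within +-0.1 of the truth more than 90% of the time, |bias| <= 0.05,
#' and RMSE <= 0.05.
#'
#' The default schedule is the reduced evaluation schedule (five chains of
#' 5,000 iterations, half discarded, no thinning): adequate because only
#' posterior means are compared, not intervals.
#'
#' @param scenario A [synthetic_scenario()].
#' @param methods Subset of `c("msgsi", "hc2step")`.
#' @param n_reps Number of replicate analyses.
#' @param mcmc An [mcmc_config()]; default is the reduced schedule above.
#' @param tau Threshold for the two-step method.
#' @param rescale Combination rule for the two-step method, see
#'   [run_hc2step()].
#' @param seed Master seed; the whole result is reproducible from it.
#' @return An `evaluation_result`: `metrics` (data frame per group x
#'   method), `estimates` (replicates x groups x methods), `truths`
#'   (replicates x groups), and the inputs.
#' @export
run_repeated_cv <- function(scenario, methods = c("msgsi", "hc2step"),
                            n_reps = 50L, mcmc = NULL, tau = 0.8,
                            rescale = "stage1_mean", seed = NULL) {
  methods <- match.arg(methods, c("msgsi", "hc2step"), several.ok = TRUE)
  mcmc <- mcmc %||% mcmc_config(n_chains = 5L, n_iter = 5000L,
                                n_burn = 2500L, thin = 1L)
  seed <- seed %||% sample.int(2147483646L, 1)
  seeds <- derive_seeds(seed, 1L + 2L * n_reps)
  study <- simulate_study(scenario, seed = seeds[1])
  rm <- study$region_map
  groups <- combined_group_names(rm)

  est <- array(NA_real_, c(n_reps, length(groups), length(methods)),
               dimnames = list(NULL, groups, methods))
  truths <- matrix(NA_real_, n_reps, length(groups),
                   dimnames = list(NULL, groups))

  for (i in seq_len(n_reps)) {
    mix_seed <- seeds[2 * i]
    fit_seed <- seeds[2 * i + 1]
    res <- tryCatch({
      syn <- with_seed(mix_seed, {
        p <- random_true_proportions(length(groups))
        synthesize_mixture(study$broad, study$regional, rm,
                           stats::setNames(p, groups),
                           scenario$mixture_size)
      })
      fit_seeds <- derive_seeds(fit_seed, length(methods))
      out <- list(truth = syn$truth$proportions)
      for (j in seq_along(methods)) {
        mc <- mcmc; mc$seed <- fit_seeds[j]
        fit <- if (methods[j] == "msgsi") {
          run_msgsi(syn$mix_broad, syn$mix_regional, syn$broad_base,
                    syn$regional_bases, rm, mcmc = mc)
        } else {
          run_hc2step(syn$mix_broad, syn$mix_regional, syn$broad_base,
                      syn$regional_bases, rm, mcmc = mc, tau = tau,
                      rescale = rescale)
        }
        out[[methods[j]]] <- posterior_means(fit)
      }
      out
    }, error = function(e) {
      stop("replicate ", i, " (seed ", mix_seed, ") failed: ",
           conditionMessage(e), call. = FALSE)
    })
    truths[i, ] <- res$truth[groups]
    for (j in seq_along(methods)) {
      est[i, , j] <- res[[methods[j]]][groups]
    }
  }

  metrics <- do.call(rbind, lapply(seq_along(methods), function(j)
    do.call(rbind, lapply(seq_along(groups), function(g) {
      data.frame(
        method = methods[j], group = groups[g],
        rmse = rmse(truths[, g], est[, g, j]),
        bias = bias(truths[, g], est[, g, j]),
        pct_deviation = pct_deviation(truths[, g], est[, g, j]),
        n = n_reps
      )
    }))))
  metrics$within_ok <- 100 - metrics$pct_deviation >= 90
  metrics$bias_ok <- abs(metrics$bias) <= 0.05
  metrics$rmse_ok <- metrics$rmse <= 0.05

  structure(
    list(metrics = metrics, estimates = est, truths = truths,
         scenario = scenario, methods = methods, mcmc = mcmc, seed = seed),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: %d replicates, methods: %s>\n",
              nrow(x$truths), paste(x$methods, collapse = ", ")))
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Estimates-versus-truth scatter for an evaluation
#'
#' One panel per method: posterior-mean estimates against true
#' proportions for every replicate and reporting group, with the identity
#' line and a +-0.1 band.
#'
#' @param result An `evaluation_result` from [run_repeated_cv()].
#' @return A ggplot object.
#' @export
plot_evaluation <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_evaluation() needs the ggplot2 package")
  }
  df <- do.call(rbind, lapply(seq_along(result$methods), function(j) {
    data.frame(
      method = result$methods[j],
      group = rep(colnames(result$truths), each = nrow(result$truths)),
      truth = as.vector(result$truths),
      estimate = as.vector(result$estimates[, , j])
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = truth, y = estimate,
                                   colour = group)) +
    ggplot2::geom_abline(intercept = 0, slope = 1) +
    ggplot2::geom_abline(intercept = c(-0.1, 0.1), slope = 1,
                         linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "true proportion", y = "posterior-mean estimate") +
    ggplot2::theme_minimal()
}
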