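#' Default penalty grid
#'
#' 20 log-spaced values in `[0.01, 1]`, returned in decreasing order (sparse
#' to dense), the order in which the stability path is evaluated.
#'
#' @param n_lambda Number of grid points.
#' @param min,max Grid range.
#' @return Decreasing numeric vector.
#' @export
default_lambda_grid <- function(n_lambda = 20, min = 0.01, max = 1)
  exp(seq(log(max), log(min), length.out = n_lambda))

#' Choose the penalty by stability selection over subsamples
#'
#' Draws `p` subsamples of size `floor(q_frac * n)` without replacement,
#' estimates a network on each at every penalty of the grid, and measures
#' edge instability
#' `D(lambda) = sum_{j<k} abar_jk (1 - abar_jk) / denominator`, where
#' `abar_jk` is the fraction of subsamples in which edge (j,k) appears.  The
#' grid is scanned from the sparse end; the selected `lambda_hat` is the
#' smallest grid value whose monotonised instability (running maximum over
#' all sparser settings) stays at or below `alpha`, i.e. the densest network
#' that is still reproducible across subsamples.  The final network is refit
#' on the full data at `lambda_hat`.
#'
#' The instability sum is normalised by the number of node pairs
#' `choose(m, 2)` by default, which makes `D` the average fraction of
#' disagreements per edge and bounds it by 0.25;
#' `denominator = "pairs_of_subsamples"` (`choose(p, 2)`) is available as an
#' alternative convention.
#'
#' @param x Count matrix, samples in rows.
#' @param measure Similarity measure, see [similarity_matrix()].
#' @param lambda_grid Penalty grid; default [default_lambda_grid()].
#' @param p Number of subsamples (default 50).
#' @param q_frac Subsample fraction (default 2/3).
#' @param alpha Instability threshold (default 0.05).
#' @param seed Integer seed for the subsample draw (required).
#' @param denominator `"pairs_of_nodes"` (default) or
#'   `"pairs_of_subsamples"`.
#' @param sigma,use_relative Passed to [similarity_matrix()].
#' @param early_stop If `TRUE`, stop descending the grid once the monotonised
#'   instability exceeds `alpha`: the selection is unchanged but the dense
#'   (expensive) end of the path is skipped; the profile then only covers the
#'   evaluated grid values.
#' @param refit Refit the full-data network at the selected penalty
#'   (default `TRUE`).
#' @param tol,max_sweeps Passed to [sparse_inverse()].
#' @return Object of class `"stability_profile"`: list with `lambda`
#'   (selected value), `profile` (data frame of `lambda`, `D`, `D_monotone`),
#'   `edge_freq` (list of mean edge-indicator matrices per evaluated
#'   `lambda`), `p`, `q`, `alpha`, `seed`, `denominator` and, when `refit`,
#'   the full-data `fit` (class `"sparse_inverse"`).
#' @examples
#' g <- make_graph("small_world", 10, seed = 1)
#' x <- simulate_counts(g, n = 40, seed = 2)$x
#' sel <- stability_select(x, "spearman", p = 10, seed = 3,
#'                         lambda_grid = default_lambda_grid(8))
#' sel$lambda
#' @export
stability_select <- function(x, measure = "spearman", lambda_grid = NULL,
                             p = 50, q_frac = 2 / 3, alpha = 0.05,
                             seed = NULL,
                             denominator = c("pairs_of_nodes",
                                             "pairs_of_subsamples"),
                             sigma = 1, use_relative = NULL,
                             early_stop = FALSE, refit = TRUE,
                             tol = 1e-4, max_sweeps = 200) {
  denominator <- match.arg(denominator)
  x <- as_count_matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid()
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (any(lambda_grid <= 0)) stop("penalties must be positive", call. = FALSE)
  q <- floor(q_frac * n)
  if (q < 3 || q >= n)
    stop("subsample size floor(q_frac * n) must lie in [3, n)", call. = FALSE)
  if (p < 2) stop("need at least 2 subsamples", call. = FALSE)
  if (is.null(seed)) stop("a seed is required for the subsample draw",
                          call. = FALSE)

  subs <- with_seed(seed,
                    lapply(seq_len(p), function(i) sort(sample.int(n, q))))
  S_list <- lapply(subs, function(idx)
    psd_repair(similarity_matrix(x[idx, , drop = FALSE], measure,
                                 sigma = sigma, use_relative = use_relative)))

  denom <- if (denominator == "pairs_of_nodes") choose(m, 2) else choose(p, 2)
  warm <- vector("list", p)
  D <- Dbar <- rep(NA_real_, length(lambda_grid))
  freq <- vector("list", length(lambda_grid))
  evaluated <- 0L
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    acc <- matrix(0, m, m)
    for (i in seq_len(p)) {
      fit <- sparse_inverse(S_list[[i]], lam, tol = tol,
                            max_sweeps = max_sweeps, A_init = warm[[i]])
      warm[[i]] <- fit$A
      acc <- acc + (fit$adjacency > 0)
    }
    abar <- acc / p
    freq[[li]] <- abar
    D[li] <- sum(abar[upper.tri(abar)] * (1 - abar[upper.tri(abar)])) / denom
    Dbar[li] <- if (li == 1) D[li] else max(Dbar[li - 1], D[li])
    evaluated <- li
    if (early_stop && Dbar[li] > alpha) break
  }

  ok <- which(Dbar[seq_len(evaluated)] <= alpha)
  if (length(ok) == 0) {
    warning("no penalty on the grid meets the instability threshold; ",
            "returning the largest grid value", call. = FALSE)
    lam_hat <- lambda_grid[1]
  } else {
    lam_hat <- lambda_grid[max(ok)]  # smallest lambda in the stable prefix
  }

  out <- list(lambda = lam_hat,
              profile = data.frame(lambda = lambda_grid[seq_len(evaluated)],
                                   D = D[seq_len(evaluated)],
                                   D_monotone = Dbar[seq_len(evaluated)]),
              edge_freq = freq[seq_len(evaluated)],
              lambda_grid = lambda_grid, p = p, q = q, alpha = alpha,
              seed = seed, denominator = denom_name(denominator))
  if (refit) {
    S <- psd_repair(similarity_matrix(x, measure, sigma = sigma,
                                      use_relative = use_relative))
    out$fit <- sparse_inverse(S, lam_hat, tol = tol, max_sweeps = max_sweeps)
  }
  structure(out, class = "stability_profile")
}

denom_name <- function(x) x

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("Stability selection: lambda = %.4g (alpha = %g, p = %d subsamples of size %d)\n",
              x$lambda, x$alpha, x$p, x$q))
  cat(sprintf("  instability at lambda_hat: D = %.4g\n",
              x$profile$D[match(x$lambda, x$profile$lambda)]))
  invisible(x)
}
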