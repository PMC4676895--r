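#' ROC/AUC of edge recovery against a known graph
#'
#' Treats the upper-triangle weights of an estimated adjacency as scores for
#' the binary edge labels of the true graph.  The AUC is the probability
#' that a randomly chosen true edge outranks a randomly chosen non-edge,
#' with ties (e.g. the many exact zeros of a sparse estimate) counted 1/2;
#' it is computed by the rank-sum formulation and coincides with the area
#' under the threshold-sweep ROC curve, where sensitivity is the proportion
#' of true edges detected and specificity the proportion of non-edges
#' correctly left out.
#'
#' @param adjacency Estimated adjacency (or fit accepted by
#'   [to_adjacency()]).
#' @param truth A [make_graph()] result (or a binary symmetric matrix of
#'   true edges) with at least one edge and one non-edge.
#' @return Object of class `"edge_recovery"`: list with `auc`, `roc` (data
#'   frame of `threshold`, `sensitivity`, `specificity`), `n_edges`,
#'   `n_nonedges`.
#' @export
edge_auc <- function(adjacency, truth) {
  A <- extract_adjacency(adjacency)
  E <- if (inherits(truth, "true_graph")) truth$edges else truth
  if (!all(dim(A) == dim(E)))
    stop("estimate and truth have different dimensions", call. = FALSE)
  scores <- A[upper.tri(A)]
  labels <- E[upper.tri(E)] > 0
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    stop("truth must contain at least one edge and one non-edge",
         call. = FALSE)
  r <- rank(scores)                       # mid-ranks handle ties as 1/2
  auc <- (sum(r[labels]) - P * (P + 1) / 2) / (P * N)

  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  last <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)  # end of each tie block
  thr <- c(Inf, s_ord[last])
  sens <- c(0, tp[last] / P)
  spec <- c(1, 1 - fp[last] / N)
  structure(list(auc = auc,
                 roc = data.frame(threshold = thr, sensitivity = sens,
                                  specificity = spec),
                 n_edges = P, n_nonedges = N),
            class = "edge_recovery")
}

#' @export
print.edge_recovery <- function(x, ...) {
  cat(sprintf("Edge recovery: AUC = %.4f (%d edges, %d non-edges)\n",
              x$auc, x$n_edges, x$n_nonedges))
  invisible(x)
}

#' Simulation benchmark of edge recovery
#'
#' For each replicate: draw a ground-truth graph, simulate counts from it,
#' build the similarity matrix, estimate the sparse inverse, and score edge
#' recovery by [edge_auc()].  Reports the mean and standard deviation of the
#' AUC over replicates.  Replicate seeds are derived from the master seed by
#' fixed offsets, so a given call is fully reproducible.
#'
#' `lambda` may be a fixed penalty or `"select"`.  Stability selection is
#' costly at scale, so with `select_once = TRUE` (default) the penalty is
#' selected on the first replicate's data and reused for the others;
#' `select_once = FALSE` re-selects per replicate.
#'
#' @param model Graph family, see [make_graph()].
#' @param m Number of taxa.
#' @param n Number of samples.
#' @param measure Similarity measure, see [similarity_matrix()].
#' @param lambda Penalty or `"select"`.
#' @param replicates Number of replicates (>= 1).
#' @param seed Master seed.
#' @param family,mu,gamma Passed to [simulate_counts()].
#' @param sigma,use_relative Passed to [similarity_matrix()].
#' @param graph_params List of extra arguments for [make_graph()].
#' @param select_args List of extra arguments for [stability_select()]
#'   (e.g. `p`, `lambda_grid`, `early_stop`).
#' @param select_once Select the penalty once and reuse it (default `TRUE`).
#' @return Data frame (one row) with `model`, `measure`, `m`, `n`,
#'   `replicates`, `lambda` (mean used), `auc_mean`, `auc_sd`; per-replicate
#'   AUCs and penalties are attached as attributes `"auc"` and `"lambda"`.
#' @examples
#' run_benchmark("small_world", m = 15, n = 100, measure = "spearman",
#'               lambda = 0.2, replicates = 2, seed = 1)
#' @export
run_benchmark <- function(model, m, n, measure, lambda, replicates = 10,
                          seed = 1, family = "negative_binomial", mu = 3,
                          gamma = 2, sigma = 1, use_relative = NULL,
                          graph_params = list(), select_args = list(),
                          select_once = TRUE) {
  stopifnot(replicates >= 1)
  aucs <- lams <- numeric(replicates)
  lam_fixed <- if (is.numeric(lambda)) lambda else NULL
  for (r in seq_len(replicates)) {
    truth <- do.call(make_graph,
                     c(list(model = model, m = m, seed = seed + 1000L + r),
                       graph_params))
    sim <- simulate_counts(truth, n, mu = mu, gamma = gamma, family = family,
                           seed = seed + 2000L + r)
    if (is.null(lam_fixed)) {
      lam_r <- do.call(stability_select,
                       c(list(x = sim$x, measure = measure,
                              seed = seed + 3000L + r, refit = FALSE,
                              sigma = sigma, use_relative = use_relative),
                         select_args))$lambda
      if (select_once) lam_fixed <- lam_r
    } else lam_r <- lam_fixed
    S <- psd_repair(similarity_matrix(sim$x, measure, sigma = sigma,
                                      use_relative = use_relative))
    fit <- sparse_inverse(S, lam_r)
    aucs[r] <- edge_auc(fit, truth)$auc
    lams[r] <- lam_r
  }
  out <- data.frame(model = model, measure = measure, m = m, n = n,
                    replicates = replicates, lambda = mean(lams),
                    auc_mean = mean(aucs), auc_sd = sd(aucs),
                    stringsAsFactors = FALSE)
  attr(out, "auc") <- aucs
  attr(out, "lambda") <- lams
  out
}
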