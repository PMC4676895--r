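#' Fit a sparse co-occurrence network to a taxa count table
#'
#' The main fitting front end.  From a samples x taxa count matrix it
#' computes the chosen taxon-taxon similarity matrix (sin-transformed rank
#' correlation or Gaussian kernel of an ecological distance), repairs it to
#' positive semidefiniteness, and estimates the l1-penalised sparse inverse,
#' whose off-diagonal support is the taxon co-occurrence network: an edge
#' means the two taxa remain associated after conditioning on all other
#' taxa.  The penalty is either supplied or chosen by stability selection
#' over subsamples (`lambda = "stars"`).
#'
#' @param x Count matrix (samples in rows) or data frame; see
#'   [read_counts()].
#' @param measure Similarity measure: `"spearman"`, `"kendall"`,
#'   `"hellinger"`, `"chi2"` or `"braycurtis"`.
#' @param lambda Non-negative penalty, or `"stars"` for stability selection.
#' @param sigma Gaussian-kernel bandwidth for distance measures (default 1).
#' @param use_relative Compute the measure on per-sample relative abundance?
#'   Default: raw counts for rank measures, relative abundance for distance
#'   measures.
#' @param min_mean If positive, drop taxa whose mean raw count falls below
#'   this threshold before fitting (see [filter_low_abundance()]); default 0
#'   (keep all).
#' @param seed Integer seed, required when `lambda = "stars"`.
#' @param tol,max_sweeps Passed to [sparse_inverse()].
#' @param ... Further arguments to [stability_select()] (`lambda_grid`, `p`,
#'   `q_frac`, `alpha`, `denominator`, `early_stop`).
#' @return Object of class `"micronet"`: list with `call`, `n`, `m`,
#'   `taxa`, `measure`, `sigma`, `use_relative`, `S` (similarity),
#'   `S_repaired`, `fit` (class `"sparse_inverse"`), `lambda`, `profile`
#'   (stability profile or `NULL`).  Methods: [print.micronet()],
#'   [summary.micronet()], [coef.micronet()], [plot.micronet()].
#' @examples
#' g <- make_graph("small_world", 12, seed = 1)
#' x <- simulate_counts(g, n = 80, seed = 2)$x
#' fit <- micronet(x, "spearman", lambda = 0.3)
#' fit
#' @export
micronet <- function(x, measure = c("spearman", "kendall", "hellinger",
                                    "chi2", "braycurtis"),
                     lambda = "stars", sigma = 1, use_relative = NULL,
                     min_mean = 0, seed = NULL, tol = 1e-4,
                     max_sweeps = 200, ...) {
  measure <- match.arg(measure)
  cl <- match.call()
  x <- as_count_matrix(x)
  if (min_mean > 0) x <- filter_low_abundance(x, min_mean)

  profile <- NULL
  if (identical(lambda, "stars")) {
    if (is.null(seed))
      stop("stability selection is randomised: supply 'seed'", call. = FALSE)
    sel <- stability_select(x, measure, seed = seed, sigma = sigma,
                            use_relative = use_relative, refit = TRUE,
                            tol = tol, max_sweeps = max_sweeps, ...)
    profile <- sel
    lam <- sel$lambda
    fit <- sel$fit
    S <- similarity_matrix(x, measure, sigma = sigma,
                           use_relative = use_relative)
    S_rep <- psd_repair(S)
  } else {
    if (!is.numeric(lambda) || lambda < 0)
      stop("'lambda' must be \"stars\" or a non-negative number",
           call. = FALSE)
    lam <- lambda
    S <- similarity_matrix(x, measure, sigma = sigma,
                           use_relative = use_relative)
    S_rep <- psd_repair(S)
    fit <- sparse_inverse(S_rep, lam, tol = tol, max_sweeps = max_sweeps)
  }

  structure(list(call = cl, n = nrow(x), m = ncol(x), taxa = colnames(x),
                 measure = measure, sigma = sigma,
                 use_relative = use_relative, S = S, S_repaired = S_rep,
                 fit = fit, lambda = lam, profile = profile),
            class = "micronet")
}

n_edges <- function(A) sum(A[upper.tri(A)] > 0)

#' @export
print.micronet <- function(x, ...) {
  A <- x$fit$adjacency
  e <- n_edges(A)
  cat("Sparse inverse-similarity co-occurrence network\n")
  cat(sprintf("  %d taxa, %d samples; measure: %s%s\n", x$m, x$n, x$measure,
              if (x$measure %in% c("hellinger", "chi2", "braycurtis"))
                sprintf(" (Gaussian kernel, sigma = %g)", x$sigma) else
                " (sin-transformed ranks)"))
  cat(sprintf("  lambda = %.4g (%s); %d edges, density %.3f\n", x$lambda,
              if (is.null(x$profile)) "fixed" else "stability-selected",
              e, e / choose(x$m, 2)))
  if (!x$fit$converged) cat("  WARNING: solver did not converge\n")
  invisible(x)
}

#' Summarise a fitted co-occurrence network
#'
#' @param object A [micronet()] fit.
#' @param ... Unused.
#' @return Object of class `"summary.micronet"` with edge counts, density,
#'   degree quantiles, isolated-taxon count, the strongest edges, and the
#'   stability profile if the penalty was selected.
#' @export
summary.micronet <- function(object, ...) {
  A <- object$fit$adjacency
  deg <- rowSums(A > 0)
  w <- A[upper.tri(A)]
  ord <- order(w, decreasing = TRUE)
  pairs <- which(upper.tri(A), arr.ind = TRUE)[ord, , drop = FALSE]
  top <- head(data.frame(taxon1 = object$taxa[pairs[, 1]],
                         taxon2 = object$taxa[pairs[, 2]],
                         weight = w[ord], stringsAsFactors = FALSE), 5)
  top <- top[top$weight > 0, , drop = FALSE]
  structure(list(m = object$m, n = object$n, measure = object$measure,
                 lambda = object$lambda, selected = !is.null(object$profile),
                 edges = n_edges(A), density = n_edges(A) / choose(object$m, 2),
                 degree_quantiles = quantile(deg, c(0, .25, .5, .75, 1)),
                 isolated = sum(deg == 0), top_edges = top,
                 converged = object$fit$converged,
                 profile = if (!is.null(object$profile))
                   object$profile$profile),
            class = "summary.micronet")
}

#' @export
print.summary.micronet <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d taxa, %d samples, measure %s\n",
              x$m, x$n, x$measure))
  cat(sprintf("  lambda %.4g (%s), %d edges (density %.3f), %d isolated taxa\n",
              x$lambda, if (x$selected) "stability-selected" else "fixed",
              x$edges, x$density, x$isolated))
  cat("  degree quantiles:",
      paste(names(x$degree_quantiles), x$degree_quantiles, sep = "=",
            collapse = " "), "\n")
  if (nrow(x$top_edges) > 0) {
    cat("  strongest edges:\n")
    for (i in seq_len(nrow(x$top_edges)))
      cat(sprintf("    %s -- %s  (%.4f)\n", x$top_edges$taxon1[i],
                  x$top_edges$taxon2[i], x$top_edges$weight[i]))
  }
  if (!x$converged) cat("  WARNING: solver did not converge\n")
  invisible(x)
}

#' Extract the estimated sparse inverse (precision) matrix
#'
#' @param object A [micronet()] fit.
#' @param ... Unused.
#' @return The m x m estimated sparse inverse of the similarity matrix; its
#'   off-diagonal zeros encode conditional independence.
#' @export
coef.micronet <- function(object, ...) object$fit$A

#' Plot a fitted co-occurrence network
#'
#' Draws the network with edge width proportional to weight; if a partition
#' is supplied (or `modules = TRUE`), nodes are coloured by module.
#'
#' @param x A [micronet()] fit.
#' @param modules `TRUE` to run [detect_modules()], or a `"taxa_partition"`.
#' @param seed Seed forwarded to [detect_modules()] and to the layout.
#' @param ... Further arguments passed to `igraph::plot.igraph`.
#' @return The igraph object, invisibly.
#' @export
plot.micronet <- function(x, modules = FALSE, seed = 1, ...) {
  A <- x$fit$adjacency
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- x$taxa
  part <- NULL
  if (inherits(modules, "taxa_partition")) part <- modules
  else if (isTRUE(modules)) part <- detect_modules(A, seed = seed)
  if (!is.null(part)) igraph::V(g)$color <- part$labels
  ew <- igraph::E(g)$weight
  lay <- with_seed(seed, igraph::layout_with_fr(g))
  igraph::plot.igraph(g, layout = lay,
                      edge.width = if (length(ew)) 1 + 3 * ew / max(ew),
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(g)
}
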