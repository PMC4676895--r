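#' Generate a ground-truth graph with its precision matrix
#'
#' Builds a binary undirected graph from one of three families that mimic
#' real biological networks, then turns it into a strictly diagonally
#' dominant (hence positive-definite) precision matrix by giving every edge
#' weight `weight` and setting each diagonal entry to the sum of the
#' absolute off-diagonal entries plus one,
#' `a_ii = sum_{j != i} |a_ij| + 1`.
#'
#' The default edge weight is -1: a negative precision entry makes linked
#' taxa *positively* associated in the resulting covariance, the natural
#' co-occurrence reading, and the one under which similarity-based recovery
#' of the edges is sign-coherent for every measure (a positive entry would
#' make linked taxa anti-correlated, which inverts distance-kernel
#' similarities).
#'
#' * `"small_world"`: Watts-Strogatz ring lattice in which each node is
#'   connected to its immediate neighbours (`2 * nei` links) with rewiring
#'   probability `p_rewire`.
#' * `"scale_free"`: Barabasi-Albert preferential attachment adding
#'   `m_attach` links per new node, giving a power-law degree distribution.
#' * `"range_dependent"`: independent edges with
#'   `P(i ~ j) = 0.9 * 0.3^(|j - i| - 1)`, so linkage decays with index
#'   distance.
#'
#' @param model `"small_world"`, `"scale_free"` or `"range_dependent"`.
#' @param m Number of nodes (taxa), at least 3.
#' @param seed Integer seed; graph generation is fully reproducible.
#' @param p_rewire Small-world rewiring probability (default 0.1).
#' @param nei Small-world neighbourhood radius (default 1, i.e. a degree-2
#'   ring before rewiring).
#' @param m_attach Scale-free links added per node (default 2).
#' @param weight Edge weight placed in the precision matrix (default -1, see
#'   Details).
#' @return Object of class `"true_graph"`: list with `edges` (binary m x m),
#'   `precision`, `model`, `m`, `seed` and the model parameters.
#' @examples
#' g <- make_graph("small_world", 10, seed = 1)
#' all(eigen(g$precision)$values > 0)
#' @export
make_graph <- function(model = c("small_world", "scale_free",
                                 "range_dependent"),
                       m, seed = NULL, p_rewire = 0.1, nei = 1,
                       m_attach = 2, weight = -1) {
  model <- match.arg(model)
  if (m < 3) stop("need at least 3 nodes", call. = FALSE)
  edges <- with_seed(seed, {
    switch(model,
      small_world = {
        g <- igraph::sample_smallworld(1, m, nei, p_rewire)
        g <- igraph::simplify(g)
        as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
      },
      scale_free = {
        g <- igraph::sample_pa(m, m = m_attach, directed = FALSE)
        g <- igraph::simplify(g)
        as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
      },
      range_dependent = {
        d <- abs(outer(seq_len(m), seq_len(m), "-"))
        prob <- 0.9 * 0.3^(d - 1)
        E <- matrix(0, m, m)
        up <- upper.tri(E)
        E[up] <- as.numeric(runif(sum(up)) < prob[up])
        E + t(E)
      })
  })
  edges[edges > 0] <- 1
  diag(edges) <- 0
  precision <- weight * edges
  diag(precision) <- rowSums(abs(precision)) + 1
  taxa <- paste0("taxon_", seq_len(m))
  dimnames(edges) <- dimnames(precision) <- list(taxa, taxa)
  structure(list(edges = edges, precision = precision, model = model,
                 m = m, seed = seed,
                 params = list(p_rewire = p_rewire, nei = nei,
                               m_attach = m_attach, weight = weight)),
            class = "true_graph")
}

#' @export
print.true_graph <- function(x, ...) {
  cat(sprintf("True graph: %s, %d nodes, %d edges (seed %s)\n",
              x$model, x$m, sum(x$edges) / 2,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Simulate counts from a known precision structure
#'
#' For each sample the log-mean vector is drawn from a multivariate normal,
#' `log(lambda_i) ~ N(mu * 1, Sigma)` with `Sigma` the inverse of the true
#' precision matrix, and counts are drawn per entry as
#' `X_ij ~ NB(mean = lambda_ij, dispersion = gamma)` with
#' `Var = lambda + lambda^2 / gamma` (`size = gamma` in R's
#' parameterisation), or `X_ij ~ Poisson(lambda_ij)`.
#'
#' @param truth A [make_graph()] result.
#' @param n Number of samples (at least 2).
#' @param mu Log-scale mean, default 3.
#' @param gamma NB overdispersion, default 2 (ignored for Poisson).
#' @param family `"negative_binomial"` or `"poisson"`.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `"sim_counts"`: list with `x` (n x m count
#'   matrix), `truth`, `mu`, `gamma`, `family`, `seed`.
#' @examples
#' g <- make_graph("range_dependent", 8, seed = 2)
#' sim <- simulate_counts(g, n = 20, seed = 3)
#' dim(sim$x)
#' @export
simulate_counts <- function(truth, n, mu = 3, gamma = 2,
                            family = c("negative_binomial", "poisson"),
                            seed = NULL) {
  family <- match.arg(family)
  if (!inherits(truth, "true_graph"))
    stop("'truth' must come from make_graph()", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  m <- truth$m
  Sigma <- solve(truth$precision)
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("precision matrix is not positive definite",
                                         call. = FALSE))
  x <- with_seed(seed, {
    Z <- matrix(rnorm(n * m), n, m)
    loglam <- mu + Z %*% R
    lam <- exp(loglam)
    cnt <- if (family == "negative_binomial")
      rnbinom(n * m, size = gamma, mu = lam)
    else
      rpois(n * m, lambda = lam)
    matrix(as.numeric(cnt), n, m)
  })
  dimnames(x) <- list(paste0("sample_", seq_len(n)), colnames(truth$edges))
  structure(list(x = x, truth = truth, mu = mu,
                 gamma = if (family == "negative_binomial") gamma else NA_real_,
                 family = family, seed = seed),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("Simulated counts: %d samples x %d taxa, %s (mu = %g%s), %s truth\n",
              nrow(x$x), ncol(x$x), x$family, x$mu,
              if (!is.na(x$gamma)) paste0(", gamma = ", x$gamma) else "",
              x$truth$model))
  invisible(x)
}
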