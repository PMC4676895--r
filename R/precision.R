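#' Repair a similarity matrix to positive semidefiniteness
#'
#' Finite-sample sin-transformed rank-correlation matrices and Bray-Curtis
#' kernels can be indefinite, while the log-determinant objective requires a
#' (semi)definite input.  Eigenvalues below `eps` are raised to `eps`, the
#' matrix is reassembled, and its diagonal renormalised to 1.  Matrices whose
#' spectrum is already above `eps` are returned exactly unchanged.
#'
#' @param S Symmetric similarity matrix with unit diagonal.
#' @param eps Eigenvalue floor, default `1e-8`.
#' @return Repaired similarity matrix (attributes preserved).
#' @export
psd_repair <- function(S, eps = 1e-8) {
  check_square_symmetric(S, "S")
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- (R + t(R)) / 2
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  attributes(R)[c("measure", "sigma")] <- attributes(S)[c("measure", "sigma")]
  dimnames(R) <- dimnames(S)
  R
}

#' Sparse inverse of a similarity matrix
#'
#' Estimates the matrix `A` minimising the penalised log-determinant
#' objective `E(A) = -log det A + tr(SA) + lambda * sum_ij |a_ij|` over
#' positive-definite matrices, by block coordinate descent on the columns of
#' `A`: each column subproblem is the l1-penalised quadratic given by the
#' stationarity conditions for the off-diagonal block (solved by cyclic
#' coordinate descent with soft-thresholding) and the diagonal entry follows
#' from its own first-order condition.  Iterations start from
#' `A0 = (S + lambda I)^{-1}`.  Zero entries of the solution encode
#' conditional independence between the corresponding taxa given all others,
#' so the support of `A` is the co-occurrence network.
#'
#' With `screen = TRUE` the exact block-diagonal screening rule is applied
#' first: the solution decouples over connected components of the graph
#' `{|S_ij| > lambda}`, and each component is solved separately, which makes
#' large sparse problems cheap without changing the answer.
#'
#' @param S Symmetric positive-(semi)definite similarity matrix with unit
#'   diagonal (apply [psd_repair()] first if in doubt).
#' @param lambda Penalty `lambda >= 0`.  At `lambda = 0` (and nonsingular
#'   `S`) the estimate is the plain inverse.
#' @param tol Convergence tolerance: mean absolute change of the entries of
#'   `A` between full sweeps.
#' @param max_sweeps Maximum number of full column sweeps; if exceeded the
#'   current iterate is returned with `converged = FALSE` and a warning.
#' @param screen Apply the block-diagonal screening rule (default `TRUE`).
#' @param A_init Optional positive-definite warm start (e.g. the solution at
#'   a neighbouring `lambda`).
#' @param zero_tol Entries with `|a_ij| < zero_tol` after convergence are
#'   snapped to exact zeros so the edge support is well defined.
#' @return Object of class `"sparse_inverse"`: a list with elements `A`
#'   (the estimated sparse inverse), `adjacency` (`|A|` with zero diagonal),
#'   `lambda`, `objective`, `objective_trace` (per-sweep objective when the
#'   problem was solved as a single block), `converged`, `sweeps`,
#'   `n_components`.
#' @examples
#' S <- diag(3); S[1, 2] <- S[2, 1] <- 0.6
#' fit <- sparse_inverse(S, lambda = 0.1)
#' fit$adjacency
#' @export
sparse_inverse <- function(S, lambda, tol = 1e-4, max_sweeps = 200,
                           screen = TRUE, A_init = NULL, zero_tol = 1e-8) {
  check_square_symmetric(S, "S")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("'lambda' must be a single non-negative number", call. = FALSE)
  S <- (S + t(S)) / 2
  m <- nrow(S)
  inner_tol <- min(tol * 1e-2, 1e-6)

  comp <- if (screen) screen_components(S, lambda) else rep(1L, m)
  ncomp <- max(comp)
  A <- matrix(0, m, m, dimnames = dimnames(S))
  converged <- TRUE
  sweeps <- 0L
  trace <- NULL
  for (cc in seq_len(ncomp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L) {
      A[idx, idx] <- 1 / (S[idx, idx] + lambda)
      next
    }
    init <- if (!is.null(A_init)) A_init[idx, idx, drop = FALSE]
    res <- tryCatch(
      .glasso_core(S[idx, idx, drop = FALSE], lambda, init, tol,
                   as.integer(max_sweeps), inner_tol),
      error = function(e)
        .glasso_core(S[idx, idx, drop = FALSE], lambda, NULL, tol,
                     as.integer(max_sweeps), inner_tol))
    A[idx, idx] <- res$A
    converged <- converged && res$converged
    sweeps <- max(sweeps, res$sweeps)
    if (length(idx) == m) trace <- res$objective_trace
  }
  if (!converged)
    warning("sparse_inverse did not converge in ", max_sweeps, " sweeps",
            call. = FALSE)

  off <- abs(A) < zero_tol
  diag(off) <- FALSE
  A[off] <- 0
  A <- (A + t(A)) / 2
  obj <- penalized_objective(A, S, lambda)
  if (is.null(trace)) trace <- obj

  structure(list(A = A, adjacency = to_adjacency(A), lambda = lambda,
                 objective = obj, objective_trace = trace,
                 converged = converged, sweeps = sweeps,
                 n_components = ncomp),
            class = "sparse_inverse")
}

# Connected components of the thresholded similarity graph |S_ij| > lambda.
# The penalised solution is exactly block diagonal over these components.
screen_components <- function(S, lambda) {
  m <- nrow(S)
  E <- abs(S) > lambda
  diag(E) <- FALSE
  if (!any(E)) return(seq_len(m))
  g <- igraph::graph_from_adjacency_matrix(E, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Penalised log-determinant objective
#'
#' Evaluates `E(A) = -log det A + tr(SA) + lambda * sum_ij |a_ij|`; used for
#' convergence diagnostics and for checking a fit against independent
#' solvers.
#'
#' @param A Symmetric positive-definite matrix.
#' @param S Similarity matrix.
#' @param lambda Penalty.
#' @return Scalar objective value (`Inf` if `A` is not positive definite).
#' @export
penalized_objective <- function(A, S, lambda) {
  ld <- determinant(A, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  -as.numeric(ld$modulus) + sum(S * A) + lambda * sum(abs(A))
}

#' Adjacency matrix of an estimated sparse inverse
#'
#' Takes elementwise absolute values and zeroes the diagonal, so edge weight
#' is the magnitude of the (negative or positive) partial-association
#' coefficient.
#'
#' @param x `"sparse_inverse"` fit, `"micronet"` fit, or a plain matrix `A`.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
to_adjacency <- function(x) {
  A <- if (inherits(x, c("sparse_inverse", "micronet")))
    extract_precision(x) else x
  A <- abs(A)
  diag(A) <- 0
  A
}

extract_precision <- function(x) {
  if (inherits(x, "micronet")) return(x$fit$A)
  if (inherits(x, "sparse_inverse")) return(x$A)
  x
}

#' Consensus of several adjacency matrices
#'
#' An edge enters the consensus iff its weight is positive in every input
#' network (set intersection of supports); the consensus weight is the
#' elementwise minimum.  Used to lower the false-positive rate by requiring
#' agreement across similarity measures.
#'
#' @param adjs List of two or more adjacency matrices over the same taxa (or
#'   fits accepted by [to_adjacency()]).
#' @param rule Only `"intersection"` is defined.
#' @return Consensus adjacency matrix.
#' @export
consensus_adjacency <- function(adjs, rule = c("intersection")) {
  rule <- match.arg(rule)
  if (!is.list(adjs) || length(adjs) < 2)
    stop("need a list of at least two adjacency matrices", call. = FALSE)
  mats <- lapply(adjs, extract_adjacency)
  dims <- vapply(mats, nrow, 1L)
  if (length(unique(dims)) != 1)
    stop("adjacency matrices have mismatched dimensions", call. = FALSE)
  nm <- lapply(mats, colnames)
  if (!all(vapply(nm, function(n) identical(n, nm[[1]]), TRUE)))
    stop("adjacency matrices cover different taxon sets", call. = FALSE)
  Reduce(pmin, mats)
}
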