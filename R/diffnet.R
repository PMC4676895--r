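#' Mean absolute distance between two networks
#'
#' `Delta = (1/(m(m-1))) * sum_{i<j} |m1_ij - m2_ij|`, computed over the
#' upper triangle of two symmetric matrices on the same taxa (adjacency or
#' similarity).  Note the normalisation is by the number of *ordered* pairs,
#' i.e. half the mean over unordered pairs, kept as conventionally defined.
#'
#' @param M1,M2 Symmetric matrices of identical dimension and taxon order.
#' @return Non-negative scalar.
#' @export
mad_statistic <- function(M1, M2) {
  M1 <- extract_adjacency(M1); M2 <- extract_adjacency(M2)
  if (!all(dim(M1) == dim(M2)))
    stop("matrices have mismatched dimensions", call. = FALSE)
  check_square_symmetric(M1, "M1"); check_square_symmetric(M2, "M2")
  m <- nrow(M1)
  sum(abs(M1[upper.tri(M1)] - M2[upper.tri(M2)])) / (m * (m - 1))
}

#' Permutation test for a differential network between two conditions
#'
#' Fits one network per condition, measures their mean absolute distance
#' [mad_statistic()] on either the similarity matrices (`basis =
#' "similarity"`) or the sparse-inverse adjacencies (`basis = "adjacency"`),
#' and assesses significance by permuting the condition labels over samples
#' and refitting both networks for each permutation.
#'
#' All distinct label assignments are enumerated exactly when their number
#' `choose(n, n1)` does not exceed `exact_limit` (exhaustive enumeration by
#' raw sample size alone is combinatorially infeasible); otherwise `n_perm`
#' Monte-Carlo permutations are drawn.  The exact p-value is the plain
#' fraction of assignments (the observed one included) with a distance at
#' least as large as observed; the Monte-Carlo p-value uses the add-one
#' estimator `(1 + B) / (1 + L)`, which cannot be zero.
#'
#' When `lambda = "select"`, the penalty is stability-selected once per
#' condition on the observed grouping and then held fixed across
#' permutations (re-selecting inside every permutation would dominate the
#' cost without changing the reference distribution materially).
#'
#' @param x Count matrix, samples in rows.
#' @param groups Factor (or named factor matching `rownames(x)`) with
#'   exactly two levels, each with at least 3 samples.
#' @param measure Similarity measure, see [similarity_matrix()].
#' @param lambda Penalty: a number, `"select"`, or `NULL` (allowed only for
#'   `basis = "similarity"`, where no sparse fit is needed).
#' @param basis `"similarity"` or `"adjacency"`.
#' @param n_perm Monte-Carlo permutation count (default 1e5).
#' @param exact_limit Enumerate exactly when `choose(n, n1) <= exact_limit`.
#' @param seed Integer seed (Monte-Carlo mode).
#' @param sigma,use_relative Passed to [similarity_matrix()].
#' @param ... Further arguments to [stability_select()] when
#'   `lambda = "select"`.
#' @return Object of class `"network_diff"`: list with `delta`, `p_value`,
#'   `basis`, `mode` (`"exact"`/`"monte_carlo"`), `n_perm` (assignments
#'   evaluated), `lambda` (per-condition penalties, if any), `null_delta`
#'   (the permutation distances), `seed`.
#' @export
permutation_test <- function(x, groups, measure = "spearman",
                             lambda = NULL,
                             basis = c("similarity", "adjacency"),
                             n_perm = 1e5, exact_limit = 1e5, seed = NULL,
                             sigma = 1, use_relative = NULL, ...) {
  basis <- match.arg(basis)
  x <- as_count_matrix(x)
  n <- nrow(x)
  if (!is.null(names(groups)) && !is.null(rownames(x)))
    groups <- groups[rownames(x)]
  groups <- factor(groups)
  if (nlevels(groups) != 2 || length(groups) != n)
    stop("'groups' must give exactly two conditions, one per sample",
         call. = FALSE)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- n - n1
  if (min(n1, n2) < 3)
    stop("each condition needs at least 3 samples", call. = FALSE)
  if (basis == "adjacency" && is.null(lambda))
    stop("'lambda' (a number or \"select\") is required for basis = \"adjacency\"",
         call. = FALSE)

  idx1_obs <- which(groups == levels(groups)[1])
  lam <- NULL
  if (basis == "adjacency") {
    if (identical(lambda, "select")) {
      if (is.null(seed)) stop("a seed is required for lambda = \"select\"",
                              call. = FALSE)
      lam <- c(stability_select(x[idx1_obs, , drop = FALSE], measure,
                                seed = seed, refit = FALSE, sigma = sigma,
                                use_relative = use_relative, ...)$lambda,
               stability_select(x[-idx1_obs, , drop = FALSE], measure,
                                seed = seed + 1L, refit = FALSE, sigma = sigma,
                                use_relative = use_relative, ...)$lambda)
    } else {
      stopifnot(is.numeric(lambda))
      lam <- rep(lambda, length.out = 2)
    }
  }

  net_for <- function(idx, pos) {
    S <- similarity_matrix(x[idx, , drop = FALSE], measure, sigma = sigma,
                           use_relative = use_relative)
    if (basis == "similarity") return(S)
    sparse_inverse(psd_repair(S), lam[pos])$adjacency
  }
  delta_for <- function(idx1)
    mad_statistic(net_for(idx1, 1L), net_for(setdiff(seq_len(n), idx1), 2L))

  delta_obs <- delta_for(idx1_obs)

  n_assign <- choose(n, n1)
  exact <- n_assign <= exact_limit
  if (exact) {
    assigns <- combn(n, n1)
    null_delta <- apply(assigns, 2, delta_for)
    p <- mean(null_delta >= delta_obs - 1e-12)
    L <- ncol(assigns)
  } else {
    if (is.null(seed)) stop("a seed is required for Monte-Carlo permutations",
                            call. = FALSE)
    null_delta <- with_seed(seed + 7L, vapply(seq_len(n_perm), function(b)
      delta_for(sample.int(n, n1)), numeric(1)))
    p <- (1 + sum(null_delta >= delta_obs - 1e-12)) / (1 + n_perm)
    L <- n_perm
  }

  structure(list(delta = delta_obs, p_value = p, basis = basis,
                 mode = if (exact) "exact" else "monte_carlo",
                 n_perm = L, lambda = lam, null_delta = null_delta,
                 seed = seed),
            class = "network_diff")
}

#' @export
print.network_diff <- function(x, ...) {
  cat(sprintf("Differential network test (%s basis): Delta = %.5g, p = %.4g (%s, %d assignments)\n",
              x$basis, x$delta, x$p_value, x$mode, x$n_perm))
  invisible(x)
}
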