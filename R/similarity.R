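#' Spearman rank correlation with mid-ranks for ties
#'
#' Product-moment correlation of mid-ranks, which reduces to the classical
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` expression when there are no ties.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`; 0 with a warning if either vector has
#'   zero variance (the correlation is undefined there).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance vector; Spearman correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Kendall's tau-b rank correlation
#'
#' `(concordant - discordant) / sqrt((T0 - T1)(T0 - T2))` with the usual tie
#' corrections `T0 = n(n-1)/2`, `T1 = sum t_k (t_k - 1) / 2` over tied-x
#' groups and `T2` likewise over tied-y groups.
#'
#' @inheritParams spearman_rho
#' @return Correlation in `[-1, 1]`; 0 with a warning when all values of
#'   either vector are tied (denominator zero).
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("all values tied; Kendall's tau undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  unname(cor(x, y, method = "kendall"))
}

#' Sin transform of a rank-correlation matrix
#'
#' Applies `sin(pi * r / 2)` elementwise.  For bivariate-normal latent
#' variables this maps rank correlations back onto the Pearson scale, which
#' is what makes the transformed matrix a similarity suitable for inversion.
#'
#' @param R Matrix (or scalar) of correlations in `[-1, 1]`.
#' @return Transformed matrix of the same shape.
#' @export
sin_transform <- function(R) {
  if (any(abs(R) > 1 + 1e-9))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  sin(pi / 2 * pmin(pmax(R, -1), 1))
}

#' Hellinger distance between two taxon profiles
#'
#' `sqrt(sum_i (sqrt(x_i1 / x_+1) - sqrt(x_i2 / x_+2))^2)` where `x_+.` are
#' the column totals: the Euclidean distance between square-rooted
#' within-column profiles, in `[0, sqrt(2)]`.
#'
#' @param x1,x2 Non-negative count vectors over the same samples.
#' @return Distance; 0 iff the two profiles are proportional.
#' @export
hellinger_distance <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  s1 <- sum(x1); s2 <- sum(x2)
  if (s1 <= 0) stop("taxon 1 has zero total count", call. = FALSE)
  if (s2 <= 0) stop("taxon 2 has zero total count", call. = FALSE)
  sqrt(sum((sqrt(x1 / s1) - sqrt(x2 / s2))^2))
}

#' Chi-square distance between two taxon profiles
#'
#' `sqrt(sum_i (x_+1 + x_+2) / (x_i1 + x_i2) * (sqrt(x_i1/x_+1) -
#' sqrt(x_i2/x_+2))^2)`; sample positions where both taxa have zero reads
#' contribute nothing (their numerator is also zero).
#'
#' @inheritParams hellinger_distance
#' @return Non-negative distance, symmetric in its arguments.
#' @export
chi2_distance <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  s1 <- sum(x1); s2 <- sum(x2)
  if (s1 <= 0) stop("taxon 1 has zero total count", call. = FALSE)
  if (s2 <= 0) stop("taxon 2 has zero total count", call. = FALSE)
  keep <- (x1 + x2) > 0
  sqrt(sum((s1 + s2) / (x1[keep] + x2[keep]) *
             (sqrt(x1[keep] / s1) - sqrt(x2[keep] / s2))^2))
}

#' Bray-Curtis dissimilarity between two taxon profiles
#'
#' `1 - 2 sum_i min(x_i1, x_i2) / (x_+1 + x_+2)`: 0 for identical vectors,
#' 1 for disjoint support.
#'
#' @inheritParams hellinger_distance
#' @return Dissimilarity in `[0, 1]`.
#' @export
braycurtis_dissimilarity <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  tot <- sum(x1) + sum(x2)
  if (tot <= 0) stop("both taxa have zero total count", call. = FALSE)
  1 - 2 * sum(pmin(x1, x2)) / tot
}

#' Gaussian kernel of a distance matrix
#'
#' `S_ij = exp(-D_ij^2 / sigma)`, turning any symmetric non-negative distance
#' matrix with zero diagonal into a similarity matrix with unit diagonal and
#' entries in `(0, 1]`.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param sigma Kernel bandwidth, positive; default 1.
#' @return Similarity matrix of the same dimension.
#' @export
gaussian_kernel <- function(D, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("'sigma' must be a positive number", call. = FALSE)
  check_square_symmetric(D, "D")
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal",
                              call. = FALSE)
  exp(-D^2 / sigma)
}

#' Taxon-taxon similarity matrix
#'
#' Computes the m x m similarity matrix between all taxon pairs of a count
#' table, either by sin-transformed rank correlation (`"spearman"`,
#' `"kendall"`) or by a Gaussian kernel of an ecological distance
#' (`"hellinger"`, `"chi2"`, `"braycurtis"`).
#'
#' Rank correlations are computed on raw counts by default (per-sample
#' normalisation can itself change within-taxon ranks); distance families
#' default to per-sample relative abundance, which adjusts for sequencing
#' depth.  Taxa with zero variance yield undefined correlations: those
#' entries are set to 0 with a warning.
#'
#' @param x Count matrix, samples in rows, or anything [as_count_matrix()]
#'   accepts.
#' @param measure One of `"spearman"`, `"kendall"`, `"hellinger"`, `"chi2"`,
#'   `"braycurtis"`.
#' @param sigma Gaussian-kernel bandwidth for the distance families.
#' @param use_relative Compute on per-sample relative abundance?  Default
#'   `NULL` means `FALSE` for rank families and `TRUE` for distance families.
#' @return Symmetric matrix with unit diagonal and attributes `measure` and
#'   `sigma`.  Kernel-family entries lie in `(0, 1]`, rank-family entries in
#'   `[-1, 1]`.
#' @examples
#' x <- matrix(rpois(60, 10), 10, 6)
#' S <- similarity_matrix(x, "hellinger")
#' range(diag(S))
#' @export
similarity_matrix <- function(x,
                              measure = c("spearman", "kendall", "hellinger",
                                          "chi2", "braycurtis"),
                              sigma = 1, use_relative = NULL) {
  measure <- match.arg(measure)
  x <- as_count_matrix(x)
  if (ncol(x) < 2) stop("need at least two taxa", call. = FALSE)
  rank_family <- measure %in% c("spearman", "kendall")
  if (is.null(use_relative)) use_relative <- !rank_family
  v <- if (use_relative) relative_abundance(x) else x

  if (rank_family) {
    const <- apply(v, 2, function(col) length(unique(col)) == 1L)
    R <- suppressWarnings(cor(v, method = measure))
    if (any(const) || anyNA(R)) {
      warning("zero-variance taxa give undefined correlations; entries set to 0: ",
              paste(colnames(v)[const], collapse = ", "), call. = FALSE)
      R[is.na(R)] <- 0
    }
    S <- sin_transform(R)
    diag(S) <- 1
  } else {
    D <- distance_matrix(v, measure)
    S <- gaussian_kernel(D, sigma)
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- list(colnames(x), colnames(x))
  attr(S, "measure") <- measure
  attr(S, "sigma") <- if (rank_family) NA_real_ else sigma
  S
}

# All-pairs distance matrix between taxon columns of v.
distance_matrix <- function(v, measure) {
  cs <- colSums(v)
  if (measure %in% c("hellinger", "chi2")) {
    zero <- cs <= 0
    if (any(zero))
      stop("taxa with zero total count have no ", measure, " profile: ",
           paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  }
  switch(measure,
    hellinger = {
      Y <- sqrt(sweep(v, 2, cs, "/"))
      G <- crossprod(Y)            # columns of Y are unit vectors
      D2 <- pmax(2 - 2 * G, 0)
      diag(D2) <- 0
      sqrt(D2)
    },
    chi2 = .chi2_distance_matrix(v),
    braycurtis = {
      if (sum(cs <= 0) >= 2)
        stop("at least two all-zero taxa: Bray-Curtis undefined for that pair",
             call. = FALSE)
      D <- as.matrix(vegan::vegdist(t(v), method = "bray"))
      dimnames(D) <- NULL
      D
    })
}
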