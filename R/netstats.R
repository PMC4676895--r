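#' Node-level network statistics
#'
#' Computes, per taxon: weighted degree `k_i = sum_j a_ij`; binary degree
#' `K_i` (number of links); triangle count `T_i = (1/2) sum_{j,k} a_ij a_ik
#' a_jk` on the binarised graph; clustering coefficient
#' `C_i = 2 T_i / (K_i (K_i - 1))` (0 when `K_i < 2`); and, given a module
#' partition, the participation coefficient
#' `Y_i = 1 - sum_M (K_i(M) / K_i)^2` (0 when `K_i = 0`), which is 0 when all
#' of a taxon's links stay inside its own module and grows as they spread
#' over modules.  Triangles and clustering are evaluated on the binarised
#' graph (edge iff weight > 0) so that the count-based `K_i (K_i - 1)`
#' normalisation is self-consistent; the weighted degree is reported
#' alongside.  Larger statistics flag better-connected, structurally more
#' important taxa.
#'
#' @param A Adjacency matrix (or fit accepted by [to_adjacency()]).
#' @param labels Optional module labels (vector or [detect_modules()]
#'   result); required for the participation coefficient.
#' @return Data frame with one row per taxon and columns `taxon`,
#'   `weighted_degree`, `binary_degree`, `triangles`, `clustering`,
#'   `participation` (NA without labels), `module` (NA without labels).
#'   The network-level clustering coefficient `C = mean(C_i)` is attached as
#'   attribute `"network_clustering"`.
#' @examples
#' tri <- matrix(1, 3, 3); diag(tri) <- 0
#' node_statistics(tri, labels = c(1, 1, 1))
#' @export
node_statistics <- function(A, labels = NULL) {
  A <- extract_adjacency(A)
  check_square_symmetric(A, "A")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal",
                              call. = FALSE)
  m <- nrow(A)
  taxa <- colnames(A)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(m))
  if (inherits(labels, "taxa_partition")) labels <- labels$labels

  B <- (A > 0) * 1
  K <- rowSums(B)
  tri <- diag(B %*% B %*% B) / 2
  clust <- ifelse(K >= 2, 2 * tri / (K * (K - 1)), 0)

  part <- module <- rep(NA_real_, m)
  if (!is.null(labels)) {
    if (length(labels) != m)
      stop("'labels' must cover all taxa", call. = FALSE)
    f <- as.integer(factor(labels))
    module <- f
    for (i in seq_len(m)) {
      if (K[i] == 0) { part[i] <- 0; next }
      km <- tapply(B[i, ], f, sum)
      part[i] <- 1 - sum((km / K[i])^2)
    }
  }

  out <- data.frame(taxon = taxa, weighted_degree = rowSums(A),
                    binary_degree = as.integer(K), triangles = tri,
                    clustering = clust, participation = part,
                    module = module, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "network_clustering") <- mean(clust)
  out
}
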