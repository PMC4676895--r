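#' Modularity of a partition
#'
#' `Q = (1/2w) * sum_ij [a_ij - k_i k_j / (2w)] delta(c_i, c_j)` with
#' `k_i = sum_j a_ij` and `w` the total edge weight.  `Q` lies in `[-1, 1]`;
#' larger values indicate better module separation, and the all-in-one
#' partition always scores 0.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal (or a
#'   fit accepted by [to_adjacency()]).
#' @param labels Module label per taxon (any vector coercible to a factor).
#' @return Scalar modularity.
#' @export
modularity_q <- function(A, labels) {
  A <- extract_adjacency(A)
  check_square_symmetric(A, "A")
  if (any(A < 0)) stop("adjacency weights must be non-negative", call. = FALSE)
  if (length(labels) != nrow(A))
    stop("'labels' must assign a module to every taxon", call. = FALSE)
  w2 <- sum(A)              # 2w
  if (w2 <= 0) stop("total edge weight is zero: modularity undefined",
                    call. = FALSE)
  f <- as.integer(factor(labels))
  k <- rowSums(A)
  q <- 0
  for (cc in unique(f)) {
    idx <- f == cc
    q <- q + sum(A[idx, idx]) / w2 - (sum(k[idx]) / w2)^2
  }
  q
}

#' Detect network modules by two-phase greedy modularity maximisation
#'
#' The classical two-step local (Louvain-type) algorithm: phase 1 repeatedly
#' moves single nodes to the neighbouring community with the largest positive
#' modularity gain until no move improves `Q`; phase 2 collapses communities
#' into super-nodes whose self-loops carry the intra-module weight; the two
#' phases repeat until the gain falls below `1e-10`.  The number of modules
#' is discovered, not prespecified.
#'
#' Node visit order in phase 1 is a fresh seeded random permutation per pass
#' (the algorithm is order dependent); ties between equal gains go to the
#' lowest community id, so a fixed seed gives a fully deterministic result.
#' Isolated taxa keep singleton modules.
#'
#' @param A Adjacency matrix (or fit accepted by [to_adjacency()]).
#' @param seed Integer seed controlling visit order (default 1).
#' @return Object of class `"taxa_partition"`: list with `labels` (named
#'   integer vector of consecutive module ids), `Q`, `n_modules`.
#' @examples
#' blocks <- matrix(0, 6, 6)
#' blocks[1:3, 1:3] <- 1; blocks[4:6, 4:6] <- 1; diag(blocks) <- 0
#' detect_modules(blocks, seed = 1)
#' @export
detect_modules <- function(A, seed = 1) {
  A <- extract_adjacency(A)
  check_square_symmetric(A, "A")
  m <- nrow(A)
  taxa <- colnames(A)
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_len(m))

  # work on an aggregated graph B whose diagonal double-counts intra-module
  # weight, so that k = rowSums(B) and w are preserved across aggregation
  B <- A
  assign_flat <- seq_len(m)       # original node -> current super-node
  w2 <- sum(A)                    # 2w, constant across phases
  if (w2 <= 0) {
    labels <- structure(seq_len(m), names = taxa)
    return(structure(list(labels = labels, Q = NA_real_, n_modules = m),
                     class = "taxa_partition"))
  }

  with_seed(seed, {
    repeat {
      nb <- nrow(B)
      comm <- seq_len(nb)
      k <- rowSums(B)
      sigma_tot <- k                 # per community: sum of member degrees
      moved_any <- FALSE
      repeat {
        moved_pass <- FALSE
        for (v in sample.int(nb)) {
          cv <- comm[v]
          # link weight from v to each community (self-loop excluded)
          wv <- B[v, ]
          wv[v] <- 0
          l <- tapply(wv, comm, sum)
          cand <- as.integer(names(l))
          # remove v from its community, then compare insertion gains.
          # Gain of putting v into community C, up to the positive constant
          # 2/w2, is l_vC - k_v * sigma_tot(C) / w2.
          sigma_tot[cv] <- sigma_tot[cv] - k[v]
          if (length(cand) == 0) {          # isolated (super-)node
            sigma_tot[cv] <- sigma_tot[cv] + k[v]
            next
          }
          lv <- l[match(cv, cand)]
          if (is.na(lv)) lv <- 0
          gains <- as.numeric(l) - k[v] * sigma_tot[cand] / w2
          gain_stay <- lv - k[v] * sigma_tot[cv] / w2
          best <- max(gains)
          if (best > gain_stay + 1e-12) {
            target <- min(cand[gains >= best - 1e-15])
          } else target <- cv
          comm[v] <- target
          sigma_tot[target] <- sigma_tot[target] + k[v]
          if (target != cv) moved_pass <- TRUE
        }
        if (!moved_pass) break
        moved_any <- TRUE
      }
      # relabel communities consecutively and aggregate
      comm <- as.integer(factor(comm))
      nc <- max(comm)
      if (!moved_any || nc == nb) break
      Bnew <- matrix(0, nc, nc)
      for (cc in seq_len(nc)) {
        idx <- comm == cc
        Bnew[cc, ] <- tapply(colSums(B[idx, , drop = FALSE]), comm, sum)
      }
      B <- (Bnew + t(Bnew)) / 2
      assign_flat <- comm[assign_flat]
    }
  })

  labels <- as.integer(factor(assign_flat))
  names(labels) <- taxa
  structure(list(labels = labels, Q = modularity_q(A, labels),
                 n_modules = max(labels)),
            class = "taxa_partition")
}

#' @export
print.taxa_partition <- function(x, ...) {
  cat(sprintf("Partition: %d modules, Q = %s\n", x$n_modules,
              if (is.na(x$Q)) "undefined (empty network)" else
                formatC(x$Q, digits = 4, format = "f")))
  sizes <- table(x$labels)
  cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}
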