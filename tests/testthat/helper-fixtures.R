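# Small graphs and count tables built in code for the unit tests.

fixture_counts <- function(n = 8, m = 5, seed = 42) {
  set.seed(seed)
  x <- matrix(rpois(n * m, lambda = 12), n, m,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(m))))
  x
}

# two unweighted k-cliques joined by a single bridge edge
fixture_two_cliques <- function(k = 4) {
  m <- 2 * k
  A <- matrix(0, m, m)
  A[seq_len(k), seq_len(k)] <- 1
  A[(k + 1):m, (k + 1):m] <- 1
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- 1
  A
}

fixture_two_triangles <- function() {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  A
}

write_fixture_tsv <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
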