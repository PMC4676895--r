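# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive every quantity from first principles and stay
# independent of the package's computational paths.

# mid-rank Spearman: Pearson correlation of hand-computed average ranks
oracle_spearman <- function(x, y) {
  # average position of equal values in the sorted order
  midrank <- function(v) sapply(v, function(vi) mean(which(sort(v) == vi)))
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Kendall tau-b by O(n^2) pair enumeration plus explicit tie counting
oracle_kendall <- function(x, y) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    num <- num + sign(x[j] - x[i]) * sign(y[j] - y[i])
  T0 <- n * (n - 1) / 2
  T1 <- sum(sapply(unique(x), function(v) {t <- sum(x == v); t * (t - 1) / 2}))
  T2 <- sum(sapply(unique(y), function(v) {u <- sum(y == v); u * (u - 1) / 2}))
  num / sqrt((T0 - T1) * (T0 - T2))
}

oracle_hellinger <- function(x1, x2)
  sqrt(sum((sqrt(x1 / sum(x1)) - sqrt(x2 / sum(x2)))^2))

oracle_chi2 <- function(x1, x2) {
  s1 <- sum(x1); s2 <- sum(x2)
  acc <- 0
  for (i in seq_along(x1)) {
    if (x1[i] + x2[i] > 0)
      acc <- acc + (s1 + s2) / (x1[i] + x2[i]) *
        (sqrt(x1[i] / s1) - sqrt(x2[i] / s2))^2
  }
  sqrt(acc)
}

oracle_braycurtis <- function(x1, x2)
  1 - 2 * sum(pmin(x1, x2)) / sum(x1 + x2)

# Proximal-gradient (ISTA) solver for the penalised log-det objective,
# independent of the block coordinate descent implementation.  Only suitable
# for small m.
oracle_penalized_inverse <- function(S, lam, iters = 50000, step = 0.05) {
  m <- nrow(S)
  A <- diag(m)
  soft <- function(M, t) sign(M) * pmax(abs(M) - t, 0)
  obj <- function(A) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    -sum(log(ev)) + sum(S * A) + lam * sum(abs(A))
  }
  cur <- obj(A)
  for (it in seq_len(iters)) {
    G <- -solve(A) + S
    t <- step
    repeat {
      Anew <- soft(A - t * G, t * lam)
      Anew <- (Anew + t(Anew)) / 2
      onew <- obj(Anew)
      if (is.finite(onew) && onew <= cur + 1e-12) break
      t <- t / 2
      if (t < 1e-12) { Anew <- A; onew <- cur; break }
    }
    if (abs(cur - onew) < 1e-12 && it > 100) { A <- Anew; break }
    A <- Anew; cur <- onew
  }
  list(A = A, objective = cur)
}

# Exhaustive modularity maximisation over all set partitions (m <= 9)
oracle_all_partitions <- function(m) {
  # restricted growth strings
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == m) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(A) {
  parts <- oracle_all_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- oracle_modularity(A, p)
    if (q > best) best <- q
  }
  best
}

# direct double-sum evaluation of the modularity formula
oracle_modularity <- function(A, labels) {
  w2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  m <- nrow(A)
  for (i in seq_len(m)) for (j in seq_len(m))
    if (labels[i] == labels[j]) q <- q + (A[i, j] - k[i] * k[j] / w2) / w2
  q
}

# AUC by brute-force concordance count over all (edge, non-edge) pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
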