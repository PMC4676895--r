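# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so that fits do not perturb user scripts.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

check_square_symmetric <- function(M, name = deparse(substitute(M)),
                                   tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(M - t(M))) > tol)
    stop(sprintf("'%s' must be symmetric (max asymmetry %.3g)",
                 name, max(abs(M - t(M)))), call. = FALSE)
  invisible(M)
}

# Coerce a counts input (matrix/data.frame) to a validated integer matrix,
# samples in rows.  Used by every function that accepts raw counts.
as_count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("counts must be a numeric matrix (samples x taxa)", call. = FALSE)
  validate_counts(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("taxon_", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  x
}

upper_tri_values <- function(M) M[upper.tri(M)]
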