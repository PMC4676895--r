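#' Read a taxa count table from delimited text
#'
#' Reads a TSV/CSV count table with sample and taxon identifiers and returns a
#' validated non-negative integer matrix oriented samples x taxa, whatever the
#' orientation of the file.
#'
#' @param path Path to a delimited text file whose first column holds row
#'   identifiers and whose first row holds column identifiers.  Lines starting
#'   with `#` are ignored.
#' @param orientation `"samples_in_rows"`, `"taxa_in_rows"`, or `"auto"`.
#'   With `"auto"` a table with more columns than rows is assumed to have taxa
#'   in columns (microbiome tables usually have many more taxa than samples
#'   when taxa are in rows).
#' @param delimiter Field delimiter, default tab.
#' @return Numeric matrix of counts, samples in rows, taxa in columns, with
#'   `rownames`/`colnames` carrying the identifiers.
#' @seealso [write_network()], [filter_low_abundance()], [relative_abundance()]
#' @export
read_counts <- function(path,
                        orientation = c("auto", "samples_in_rows",
                                        "taxa_in_rows"),
                        delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = delimiter, row.names = 1,
                    check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  x <- as.matrix(tab)
  if (!is.numeric(x)) stop("count table contains non-numeric cells",
                           call. = FALSE)
  # auto-detect: taxa usually far outnumber samples, so the longer axis is
  # taken to be taxa (ties read as samples-in-rows)
  if (orientation == "auto")
    orientation <- if (ncol(x) >= nrow(x)) "samples_in_rows" else "taxa_in_rows"
  if (orientation == "taxa_in_rows") x <- t(x)
  validate_counts(x)
  storage.mode(x) <- "double"
  x
}

#' Validate a count matrix
#'
#' Checks that all entries are non-negative integers and that sample/taxon
#' identifiers are unique, naming the offending cell on failure.
#'
#' @param x Numeric matrix, samples in rows.
#' @return `x`, invisibly.
#' @export
validate_counts <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 samples and 2 taxa", call. = FALSE)
  bad <- which(x < 0 | abs(x - round(x)) > 1e-8 | !is.finite(x),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    rn <- if (!is.null(rownames(x))) rownames(x)[i] else i
    cn <- if (!is.null(colnames(x))) colnames(x)[j] else j
    stop(sprintf("counts must be non-negative integers; offending entry %s at sample '%s', taxon '%s'",
                 format(x[i, j]), rn, cn), call. = FALSE)
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Read a sample-to-group table
#'
#' Two-column delimited file (sample id, group label); returns a named factor
#' in the order of the file.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, default tab.
#' @param header Does the file carry a header row?  Default `TRUE`.
#' @return Named factor of group labels.
#' @export
read_groups <- function(path, delimiter = "\t", header = TRUE) {
  if (!file.exists(path)) stop("group file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = header, sep = delimiter,
                    check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("group file needs two columns (sample, group)",
                          call. = FALSE)
  structure(factor(tab[[2]]), names = as.character(tab[[1]]))
}

#' Drop taxa below a mean-abundance threshold
#'
#' Keeps exactly the taxa whose mean raw count over all samples is at least
#' `min_mean` (the usual pre-filter before network construction, e.g. a mean
#' of two reads), preserving column order.  Idempotent.
#'
#' @param x Count matrix, samples in rows.
#' @param min_mean Minimum column mean (raw reads); non-negative.
#' @return The filtered count matrix.
#' @export
filter_low_abundance <- function(x, min_mean = 2) {
  x <- as_count_matrix(x)
  if (!is.numeric(min_mean) || min_mean < 0)
    stop("'min_mean' must be a non-negative number", call. = FALSE)
  keep <- colMeans(x) >= min_mean
  if (!any(keep))
    stop("all taxa fall below the abundance threshold; no network can be built",
         call. = FALSE)
  x[, keep, drop = FALSE]
}

#' Per-sample relative abundance
#'
#' Divides each sample row by its total read count.  All-zero samples stay
#' all-zero and trigger a warning rather than an error, so sample counts keep
#' matching any group-label file.
#'
#' @param x Count matrix, samples in rows.
#' @return Matrix of proportions in `[0, 1]`; non-degenerate rows sum to 1.
#' @export
relative_abundance <- function(x) {
  x <- as_count_matrix(x)
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero)) {
    warning("all-zero sample(s) kept as all-zero rows: ",
            paste(rownames(x)[zero], collapse = ", "), call. = FALSE)
    rs[zero] <- 1
  }
  x / rs
}

#' Write a network to disk
#'
#' Writes a symmetric zero-diagonal weighted adjacency matrix either as a
#' plain edge list (`taxonA<TAB>taxonB<TAB>weight`, one row per pair `i < j`
#' with positive weight) or as GraphML (nodes carry taxon ids and, if given,
#' module labels).
#'
#' @param adjacency Symmetric non-negative matrix with zero diagonal, or a
#'   [sparse_inverse()] / [micronet()] result.
#' @param path Output file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @param taxon_ids Node names; defaults to the matrix column names.
#' @param modules Optional module labels (e.g. from [detect_modules()]),
#'   written as a node attribute in GraphML output.
#' @param comment Optional character vector written as leading `#` comment
#'   lines (edge-list format only); used by the command-line driver to record
#'   run parameters.
#' @return `path`, invisibly.
#' @export
write_network <- function(adjacency, path,
                          format = c("edge_list", "graphml"),
                          taxon_ids = NULL, modules = NULL, comment = NULL) {
  format <- match.arg(format)
  A <- extract_adjacency(adjacency)
  check_square_symmetric(A, "adjacency")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal",
                              call. = FALSE)
  m <- nrow(A)
  if (is.null(taxon_ids)) taxon_ids <- colnames(A)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(m))
  if (format == "edge_list") {
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    el <- data.frame(from = taxon_ids[idx[, 1]], to = taxon_ids[idx[, 2]],
                     weight = A[idx], stringsAsFactors = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    writeLines(paste0("# nodes: ", paste(taxon_ids, collapse = ",")), con)
    if (nrow(el) > 0)
      writeLines(paste(el$from, el$to,
                       formatC(el$weight, digits = 17, format = "g"),
                       sep = "\t"), con)
  } else {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- taxon_ids
    if (!is.null(modules)) {
      lab <- if (inherits(modules, "taxa_partition")) modules$labels else modules
      igraph::V(g)$module <- as.integer(lab)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list network back into an adjacency matrix
#'
#' Inverse of [write_network()]'s edge-list format.  The full node set is
#' recovered from the `# nodes:` header (so isolated taxa survive a round
#' trip) or can be supplied explicitly.
#'
#' @param path Edge-list file written by [write_network()].
#' @param taxon_ids Optional character vector of node names overriding the
#'   header.
#' @return Symmetric weighted adjacency matrix with zero diagonal.
#' @export
read_network <- function(path, taxon_ids = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (is.null(taxon_ids)) {
    hdr <- grep("^# nodes: ", lines, value = TRUE)
    if (length(hdr) == 0)
      stop("no '# nodes:' header and no 'taxon_ids' given", call. = FALSE)
    taxon_ids <- strsplit(sub("^# nodes: ", "", hdr[1]), ",")[[1]]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  A <- matrix(0, length(taxon_ids), length(taxon_ids),
              dimnames = list(taxon_ids, taxon_ids))
  if (length(body) > 0) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    i <- match(parts[, 1], taxon_ids); j <- match(parts[, 2], taxon_ids)
    if (anyNA(i) || anyNA(j))
      stop("edge list mentions taxa absent from the node set", call. = FALSE)
    w <- as.numeric(parts[, 3])
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

# Accept a plain matrix, a sparse_inverse fit, or a micronet fit wherever an
# adjacency is expected.
extract_adjacency <- function(x) {
  if (inherits(x, "micronet")) return(x$fit$adjacency)
  if (inherits(x, "sparse_inverse")) return(x$adjacency)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as an adjacency matrix", call. = FALSE)
}
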