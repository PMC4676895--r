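test_that("count tables round-trip through disk in either orientation", {
  x <- fixture_counts(n = 3, m = 4)
  p1 <- tempfile(fileext = ".tsv")
  write_fixture_tsv(x, p1)
  got <- read_counts(p1, orientation = "samples_in_rows")
  expect_identical(dim(got), dim(x))
  expect_equal(unname(got), unname(x))
  expect_identical(colnames(got), colnames(x))

  # taxa-in-rows file read with the other flag gives the same matrix
  p2 <- tempfile(fileext = ".tsv")
  tx <- t(x)
  df <- data.frame(taxon = rownames(tx), tx, check.names = FALSE)
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- read_counts(p2, orientation = "taxa_in_rows")
  expect_equal(got2[rownames(x), colnames(x)], x)

  # auto-detection: 4 taxa > 3 samples, so the wide file is samples-in-rows
  expect_equal(unname(read_counts(p1)), unname(x))
})

test_that("validation rejects negatives, non-integers and duplicate ids", {
  x <- fixture_counts(n = 3, m = 4)
  x[2, 3] <- -2
  p <- tempfile(fileext = ".tsv")
  write_fixture_tsv(x, p)
  expect_error(read_counts(p, "samples_in_rows"), "s2.*t3")

  y <- fixture_counts()
  y[1, 1] <- 1.5
  expect_error(validate_counts(y), "non-negative integers")

  z <- fixture_counts()
  colnames(z) <- c("a", "a", "b", "c", "d")
  expect_error(validate_counts(z), "duplicate taxon")
})

test_that("abundance filter keeps exactly the taxa at or above the mean threshold", {
  # column means 1.9, 2.0, 5.0 over 10 samples
  x <- cbind(t1 = c(rep(2, 9), 1), t2 = rep(2, 10), t3 = rep(5, 10))
  rownames(x) <- paste0("s", 1:10)
  expect_equal(unname(colMeans(x)), c(1.9, 2, 5))
  kept <- filter_low_abundance(x, 2)
  expect_identical(colnames(kept), c("t2", "t3"))

  # (0,0,1) has mean 1/3 < 2
  y <- cbind(t1 = c(0, 0, 1), t2 = c(5, 5, 5))
  rownames(y) <- paste0("s", 1:3)
  expect_identical(colnames(filter_low_abundance(y, 2)), "t2")

  # threshold 0 keeps everything; the filter is idempotent
  expect_equal(filter_low_abundance(x, 0), x)
  expect_equal(filter_low_abundance(kept, 2), kept)
  expect_error(filter_low_abundance(x, 100), "all taxa")
})

test_that("relative abundance normalises rows and flags degenerate samples", {
  x <- rbind(c(2, 2, 4), c(1, 1, 2))
  colnames(x) <- paste0("t", 1:3); rownames(x) <- paste0("s", 1:2)
  p <- relative_abundance(x)
  expect_equal(p[1, ], c(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  expect_equal(unname(rowSums(p)), c(1, 1))

  x0 <- rbind(c(0, 0, 0), c(1, 2, 1))
  colnames(x0) <- paste0("t", 1:3); rownames(x0) <- c("empty", "ok")
  expect_warning(p0 <- relative_abundance(x0), "all-zero")
  expect_equal(unname(p0[1, ]), c(0, 0, 0))
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("networks round-trip through the edge-list format exactly", {
  A <- matrix(0, 4, 4, dimnames = rep(list(paste0("t", 1:4)), 2))
  A[1, 2] <- A[2, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- 1.25
  A[1, 3] <- A[3, 1] <- 0.125   # taxon 4 isolated
  p <- tempfile(fileext = ".tsv")
  write_network(A, p)
  expect_equal(read_network(p), A)

  # triangle has exactly 3 edge records
  expect_length(grep("^[^#]", readLines(p)), 3L)

  # empty network: valid file, empty edge section
  E <- matrix(0, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  p2 <- tempfile(fileext = ".tsv")
  write_network(E, p2)
  expect_equal(read_network(p2), E)

  bad <- A; bad[1, 2] <- 9
  expect_error(write_network(bad, tempfile()), "symmetric")
})

test_that("graphml output carries taxon names and module labels", {
  A <- fixture_two_triangles()
  dimnames(A) <- rep(list(paste0("g", 1:6)), 2)
  part <- detect_modules(A, seed = 1)
  p <- tempfile(fileext = ".graphml")
  write_network(A, p, format = "graphml", modules = part)
  g <- igraph::read_graph(p, format = "graphml")
  expect_setequal(igraph::V(g)$name, paste0("g", 1:6))
  expect_length(unique(igraph::V(g)$module), 2L)
})

test_that("group files are read as named factors", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup", "s1\tgut", "s2\tskin", "s3\tgut"), p)
  g <- read_groups(p)
  expect_identical(unname(as.character(g)), c("gut", "skin", "gut"))
  expect_identical(names(g), c("s1", "s2", "s3"))
})
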