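test_that("expression matrices load from TSV with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\t4", "G2\t2\t5", "G3\t3\t6"), path)
  m <- load_expression(path, "tpm")
  expect_equal(dim(m$values), c(3L, 2L))
  expect_equal(gene_ids(m), c("G1", "G2", "G3"))
  expect_equal(sample_ids(m), c("S1", "S2"))
  expect_equal(m$scale, "tpm")
  expect_equal(m$values["G2", "S2"], 5)

  writeLines(c("gene_id\tS1", "G1\t1", "G1\t2"), path)
  expect_error(load_expression(path, "tpm"), "duplicate gene id")

  writeLines(c("gene_id\tS1", "G1\tabc"), path)
  expect_error(load_expression(path, "tpm"), "non-numeric.*G1.*S1")

  writeLines("gene_id\tS1\tS2", path)
  empty <- load_expression(path, "tpm")
  expect_equal(nrow(empty$values), 0L)
  expect_s3_class(empty, "expr_matrix")
})

test_that("GCT preamble and Description column are tolerated", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t2", "Name\tDescription\tS1\tS2",
               "G1\tfoo\t1\t2", "G2\tbar\t3\t4"), path)
  m <- load_expression(path, "counts")
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(m$values["G2", "S1"], 3)
})

test_that("zero replacement and log2 transform follow the global minimum rule", {
  m <- expression_matrix(matrix(c(0, 2, 8), 3, 1,
    dimnames = list(c("G1", "G2", "G3"), "S1")), "tpm")
  out <- replace_zeros_and_log2(m)
  expect_equal(unname(out$values[, 1]), c(1, 1, 3))
  expect_equal(out$scale, "log2")

  nz <- expression_matrix(matrix(c(2, 4, 8, 16), 2, 2,
    dimnames = list(c("G1", "G2"), c("S1", "S2"))), "tpm")
  expect_equal(replace_zeros_and_log2(nz)$values, log2(nz$values))

  allz <- expression_matrix(matrix(0, 2, 2,
    dimnames = list(c("G1", "G2"), c("S1", "S2"))), "tpm")
  expect_error(replace_zeros_and_log2(allz), "no non-zero")
})

test_that("log2 transform preserves value ordering of non-zero entries", {
  set.seed(42)
  v <- matrix(round(rexp(60, 0.2)), 12, 5,
              dimnames = list(sprintf("G%02d", 1:12), sprintf("S%d", 1:5)))
  out <- replace_zeros_and_log2(expression_matrix(v, "tpm"))
  for (j in 1:5) {
    nz <- v[, j] > 0
    expect_equal(order(out$values[nz, j]), order(v[nz, j]))
  }
})

test_that("zero-SD genes are removed and reported, order preserved", {
  v <- rbind(G1 = c(5, 5, 5), G2 = c(5, 5, 6), G3 = c(1, 1, 1),
             G4 = c(2, 9, 4))
  colnames(v) <- paste0("S", 1:3)
  res <- filter_zero_sd_genes(expression_matrix(v, "tpm"))
  expect_equal(gene_ids(res$matrix), c("G2", "G4"))
  expect_equal(res$report$removed_zero_sd, c("G1", "G3"))

  allc <- expression_matrix(matrix(7, 3, 2,
    dimnames = list(paste0("G", 1:3), paste0("S", 1:2))), "tpm")
  res2 <- filter_zero_sd_genes(allc)
  expect_equal(nrow(res2$matrix$values), 0L)
  expect_equal(res2$report$removed_zero_sd, paste0("G", 1:3))
})

test_that("gene-id filters act on suffix and deprecated stable ids", {
  v <- matrix(1:8, 4, 2,
    dimnames = list(c("ENSG000001.5_PAR_Y", "ENSG000002.1", "G7", "G8"),
                    c("S1", "S2")))
  m <- expression_matrix(v, "counts")
  res <- filter_gene_ids(m, suffix = "_PAR_Y", deprecated = "G7")
  expect_equal(gene_ids(res$matrix), c("ENSG000002.1", "G8"))
  expect_equal(res$report$removed_suffix, "ENSG000001.5_PAR_Y")
  expect_equal(res$report$removed_deprecated, "G7")

  ident <- filter_gene_ids(m, suffix = "_NOPE", deprecated = character())
  expect_equal(ident$matrix$values, m$values)

  # versioned ids match deprecated stable ids after truncation
  res2 <- filter_gene_ids(m, suffix = "", deprecated = "ENSG000002")
  expect_equal(res2$report$removed_deprecated, "ENSG000002.1")
})

test_that("cell-line samples are dropped via metadata", {
  v <- matrix(1:10, 2, 5, dimnames = list(c("G1", "G2"), paste0("S", 1:5)))
  m <- expression_matrix(v, "counts")
  meta <- sample_metadata(paste0("S", 1:5), rep("liver", 5),
                          c(FALSE, TRUE, FALSE, TRUE, FALSE))
  res <- drop_cell_line_samples(m, meta)
  expect_equal(sample_ids(res$matrix), c("S1", "S3", "S5"))
  expect_equal(res$report$removed_cell_line_samples, c("S2", "S4"))

  none <- drop_cell_line_samples(m, sample_metadata(paste0("S", 1:5),
                                                    rep("liver", 5), FALSE))
  expect_equal(none$matrix$values, m$values)

  expect_error(drop_cell_line_samples(m,
    sample_metadata(paste0("S", 1:4), rep("liver", 4), FALSE)), "S5")
})

test_that("filters partition inputs: removed plus retained equals input", {
  set.seed(3)
  v <- matrix(rpois(80, 5), 16, 5,
              dimnames = list(sprintf("G%02d", 1:16), paste0("S", 1:5)))
  v[3, ] <- 4; v[11, ] <- 0
  m <- expression_matrix(v, "counts")
  res <- filter_zero_sd_genes(m)
  expect_length(c(gene_ids(res$matrix), res$report$removed_zero_sd), 16L)
  expect_length(intersect(gene_ids(res$matrix),
                          res$report$removed_zero_sd), 0L)
  res2 <- filter_gene_ids(m, "_PAR_Y", c("G05", "G09"))
  got <- c(gene_ids(res2$matrix), res2$report$removed_suffix,
           res2$report$removed_deprecated)
  expect_setequal(got, gene_ids(m))
})
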