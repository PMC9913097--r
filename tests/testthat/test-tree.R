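mk_expr <- function(v) {
  dimnames(v) <- list(sprintf("G%d", seq_len(nrow(v))),
                      sprintf("S%d", seq_len(ncol(v))))
  expression_matrix(v, "log2")
}

test_that("Pearson correlations match hand-computed values", {
  m <- mk_expr(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 3, 2, 1)))
  cm <- pearson_matrix(m, "genes")
  expect_equal(cm$r["G1", "G1"], 1)
  expect_equal(cm$r["G1", "G2"], 0.8)     # hand evaluation of the formula
  expect_equal(cm$r["G1", "G3"], -1)
  expect_equal(cm$r, t(cm$r))

  const <- mk_expr(rbind(c(1, 1, 1), c(1, 2, 3)))
  expect_error(pearson_matrix(const, "genes"), "G1")
})

test_that("sample-axis correlation transposes the computation", {
  set.seed(2)
  m <- mk_expr(matrix(rnorm(40), 10, 4))
  cs <- pearson_matrix(m, "samples")
  expect_equal(cs$ids, sample_ids(m))
  expect_equal(unname(cs$r), unname(cor(m$values)))
})

test_that("d = 1 - r maps the correlation endpoints and is invertible", {
  m <- mk_expr(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1), c(1, 3, 2)))
  cm <- pearson_matrix(m, "genes")
  dm <- corr_to_distance(cm)
  expect_equal(dm$d["G1", "G2"], 0)   # complete correlation
  expect_equal(dm$d["G1", "G3"], 2)   # complete anti-correlation
  expect_equal(diag(dm$d), setNames(rep(0, 4), gene_ids(m)))
  expect_true(all(dm$d >= 0 & dm$d <= 2))
  off <- upper.tri(dm$d)
  expect_equal((1 - dm$d)[off], cm$r[off])
})

test_that("UPGMA reproduces the hand-executed three-leaf merge", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgma(dist_matrix(d))
  h <- node_heights(phy)
  expect_equal(sort(h[h > 0]), c(1, 4))  # merge heights 2/2 and 8/2
  cm <- cophenetic_matrix(phy)$d
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 8)
  expect_equal(cm["B", "C"], 8)
})

test_that("a two-leaf tree is a cherry with half-distance branches", {
  d <- matrix(c(0, 1.4, 1.4, 0), 2, 2,
              dimnames = list(c("X", "Y"), c("X", "Y")))
  phy <- upgma(dist_matrix(d))
  expect_equal(sort(phy$tip.label), c("X", "Y"))
  expect_equal(unname(phy$edge.length), c(0.7, 0.7))
})

test_that("UPGMA matches the brute-force average-linkage oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    d <- random_dist_matrix(n)
    mine <- cophenetic_matrix(upgma(dist_matrix(d)))$d
    ref <- oracle_upgma_cophenetic(d)
    expect_matrix_equal(mine, ref, tol = 1e-9)
  }
})

test_that("equidistant leaves give the same cophenetic matrix in any input order", {
  d <- matrix(1.2, 5, 5); diag(d) <- 0
  labs <- c("e", "a", "d", "b", "c")
  dimnames(d) <- list(labs, labs)
  cm1 <- cophenetic_matrix(upgma(dist_matrix(d)))$d
  perm <- c("a", "b", "c", "d", "e")
  cm2 <- cophenetic_matrix(upgma(dist_matrix(d[perm, perm])))$d
  expect_matrix_equal(cm1[perm, perm], cm2, tol = 1e-12)
  expect_true(all(cm1[upper.tri(cm1)] == 1.2))
})

test_that("UPGMA trees are ultrametric and cophenetic values are bounded", {
  set.seed(77)
  for (i in 1:10) {
    d <- random_dist_matrix(sample(5:12, 1))
    phy <- upgma(dist_matrix(d))
    depth <- ape::node.depth.edgelength(phy)
    tips <- seq_along(phy$tip.label)
    expect_lt(max(abs(depth[tips] - mean(depth[tips]))), 1e-9)
    cm <- cophenetic_matrix(phy)$d[rownames(d), colnames(d)]
    off <- upper.tri(d)
    expect_true(all(cm[off] >= min(d[off]) - 1e-9))
    expect_true(all(cm[off] <= max(d[off]) + 1e-9))
  }
})

test_that("an ultrametric input matrix is a fixed point of UPGMA", {
  set.seed(13)
  for (i in 1:5) {
    phy0 <- random_ultrametric_tree(8)
    d <- as.matrix(cophenetic(phy0))
    cm <- cophenetic_matrix(upgma(dist_matrix(d)))$d
    expect_matrix_equal(cm, d[rownames(cm), colnames(cm)], tol = 1e-9)
  }
})

test_that("distance_fit_summary compares original and tree distances", {
  set.seed(9)
  d <- random_dist_matrix(10)
  phy <- upgma(dist_matrix(d))
  fit <- distance_fit_summary(dist_matrix(d), phy)
  expect_equal(fit$n_pairs, choose(10, 2))
  expect_gt(fit$correlation, 0)
  # on an already-ultrametric input the tree reproduces the distances
  du <- as.matrix(cophenetic(random_ultrametric_tree(9)))
  fit2 <- distance_fit_summary(dist_matrix(du), upgma(dist_matrix(du)))
  expect_equal(fit2$mean_cophenetic, fit2$mean_original, tolerance = 1e-9)
  expect_equal(fit2$correlation, 1, tolerance = 1e-9)
})
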