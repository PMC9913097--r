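test_that("hypergeometric upper tail matches enumeration on the worked case", {
  expect_equal(hypergeom_pvalue(10, 4, 5, 0), 1)
  expect_equal(hypergeom_pvalue(10, 4, 5, 4), 6 / 252, tolerance = 1e-12)
  expect_error(hypergeom_pvalue(10, 4, 5, 5), "k <= min")
  expect_error(hypergeom_pvalue(10, 11, 5, 2), "K <= N")
})

test_that("hypergeometric p-values agree with exhaustive enumeration", {
  for (N in c(5, 8, 10)) {
    for (n in c(2, N %/% 2, N - 1)) {
      for (K in c(1, N %/% 3, N)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_pvalue(N, K, n, k),
                       oracle_hyper_upper(N, K, n, k), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("p decreases as the hit count grows", {
  p <- vapply(0:10, function(k) hypergeom_pvalue(50, 10, 20, k), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("BH adjustment executes the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(61)
  p <- runif(25)
  adj <- bh_fdr(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p))
  # invariant to input order
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  # non-decreasing along sorted p
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("enrichment rows carry the reporting statistics", {
  universe <- sprintf("U%04d", 1:1000)
  term <- universe[1:387]
  clade <- c(universe[1:180], universe[500:799])  # k=180, n=480
  lib <- term_library(list(OLF = list(description = "smell", genes = term)))
  rows <- enrich(clade, lib, universe, alpha = Inf)
  expect_equal(rows$k, 180L)
  expect_equal(rows$K, 387L)
  expect_equal(round(rows$hit_percent, 1), 46.5)

  uni2 <- sprintf("G%03d", 1:100)
  lib2 <- term_library(list(T = list(description = "t", genes = uni2[1:10])))
  clade2 <- c(uni2[1:8], uni2[50:61])  # k=8, n=20, K=10, N=100
  r2 <- enrich(clade2, lib2, uni2, alpha = Inf)
  expect_equal(r2$expected, 2)
  expect_equal(r2$over_representation, 4)
  expect_equal(r2$hit_percent, 80)
})

test_that("terms without clade hits are neither tested nor counted in m", {
  uni <- sprintf("G%02d", 1:40)
  lib <- term_library(list(
    HIT = list(description = "", genes = uni[1:8]),
    MISS = list(description = "", genes = uni[30:35])))
  rows <- enrich(uni[1:10], lib, uni, alpha = Inf)
  expect_equal(rows$term_id, "HIT")
  expect_equal(attr(rows, "n_tested"), 1L)
  # and an all-miss clade yields an empty, well-formed result
  none <- enrich(uni[25:28], term_library(
    list(X = list(description = "", genes = uni[1:5]))), uni)
  expect_equal(nrow(none), 0L)
  expect_error(enrich(c("NOT_IN_UNIVERSE"), lib, uni), "not in the universe")
  expect_error(enrich(uni[1], lib, character(0)), "empty")
})

test_that("results rank by ascending p and a planted module term ranks first", {
  sim <- make_module_matrix(3, 10, 30, 100, within_r = 0.9, seed = 71)
  tree <- build_coexpression_tree(sim$matrix, "genes")
  driver <- sim$modules$MOD2[1]
  clade <- default_clade(tree, driver)
  lib <- make_term_library(sim$modules, gene_ids(sim$matrix), seed = 72)
  rows <- enrich(clade$gene_ids, lib, gene_ids(sim$matrix), alpha = Inf)
  expect_true(all(diff(rows$p) >= 0))
  expect_equal(rows$term_id[1], "TERM_MOD2")
})

test_that("versioned identifiers match on stable ids", {
  uni <- c("ENSG01", "ENSG02", "ENSG03", "ENSG04")
  lib <- term_library(list(T = list(description = "",
                                    genes = c("ENSG01.7", "ENSG02"))))
  rows <- enrich(c("ENSG01.2", "ENSG03.1"), lib, paste0(uni, ".9"),
                 alpha = Inf)
  expect_equal(rows$k, 1L)
  expect_equal(rows$K, 2L)
})
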