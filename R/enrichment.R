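#' Gene term library
#'
#' @param terms Named list; each element is a list with a `description`
#'   string and a character vector `genes` (non-empty).
#' @param category Category label (e.g. "GO biological process").
#' @return A `term_library` object.
#' @export
term_library <- function(terms, category = "custom") {
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("terms must be uniquely named by term id")
  for (id in names(terms)) {
    t <- terms[[id]]
    if (is.null(t$genes) || !length(t$genes))
      stop("term '", id, "' has an empty gene set")
    terms[[id]]$genes <- unique(strip_gene_version(as.character(t$genes)))
    if (is.null(t$description)) terms[[id]]$description <- ""
  }
  structure(list(category = category, terms = terms), class = "term_library")
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf("term_library '%s': %d terms\n", x$category, length(x$terms)))
  invisible(x)
}

#' Hypergeometric upper-tail p-value for term over-representation
#'
#' Probability of observing at least `k` term genes in a clade of size `n`
#' drawn from a universe of `N` genes of which `K` carry the term:
#' P(X >= k) for X ~ Hypergeometric(N, K, n). Evaluated via the
#' log-space distribution function for numerical stability at extreme
#' values.
#'
#' @param N Universe size.
#' @param K Term size in the universe.
#' @param n Clade size counted in the universe.
#' @param k Observed clade hits.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_pvalue(10, 4, 5, 4)  # 6/252
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
    stop("require 0 <= k <= min(n, K), K <= N, n <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' p_adj(i) = min over j >= i of min(1, p(j) * m / j), returned in the
#' original input order.
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Term enrichment of a clade gene list
#'
#' For every library term with at least one clade hit, counts are computed
#' restricted to the declared gene universe, the hypergeometric upper-tail
#' p-value is evaluated, and p-values are BH-adjusted across all tested
#' terms (terms without hits are not tested and do not count towards the
#' family size m). Rows with adjusted p above `alpha` are dropped and the
#' remainder ranked by raw p ascending; ties break by descending
#' over-representation rate, then term id. Gene identifiers are matched
#' case-sensitively on stable ids (versions stripped).
#'
#' @param clade_genes Character vector of clade gene ids (subset of
#'   `universe` after version stripping).
#' @param lib A [term_library()].
#' @param universe Character vector: all genes eligible for draw, normally
#'   every gene in the coexpression tree.
#' @param alpha FDR threshold for reporting (default 0.05; `Inf` reports
#'   every tested term).
#' @return A data frame with columns `term_id`, `description`, `p`,
#'   `p_adj`, `k`, `n`, `K`, `N`, `expected`, `over_representation`,
#'   `hit_percent`; attribute `n_tested` records the BH family size.
#' @export
enrich <- function(clade_genes, lib, universe, alpha = 0.05) {
  stopifnot(inherits(lib, "term_library"))
  universe <- unique(strip_gene_version(as.character(universe)))
  if (!length(universe)) stop("empty gene universe")
  clade_genes <- unique(strip_gene_version(as.character(clade_genes)))
  outside <- setdiff(clade_genes, universe)
  if (length(outside))
    stop("clade gene(s) not in the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(clade_genes)

  rows <- lapply(names(lib$terms), function(id) {
    tg <- intersect(lib$terms[[id]]$genes, universe)
    K <- length(tg)
    k <- length(intersect(clade_genes, tg))
    if (k == 0L) return(NULL)
    expected <- n * K / N
    data.frame(term_id = id, description = lib$terms[[id]]$description,
               p = hypergeom_pvalue(N, K, n, k), p_adj = NA_real_,
               k = k, n = n, K = K, N = N, expected = expected,
               over_representation = k / expected,
               hit_percent = 100 * k / K, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(term_id = character(), description = character(),
                       p = numeric(), p_adj = numeric(), k = integer(),
                       n = integer(), K = integer(), N = integer(),
                       expected = numeric(), over_representation = numeric(),
                       hit_percent = numeric(), stringsAsFactors = FALSE)
    attr(rows, "n_tested") <- 0L
    return(rows)
  }
  m <- nrow(rows)
  rows$p_adj <- bh_fdr(rows$p)
  rows <- rows[rows$p_adj <= alpha, , drop = FALSE]
  rows <- rows[order(rows$p, -rows$over_representation, rows$term_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "n_tested") <- m
  rows
}
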