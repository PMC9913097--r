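#' Synthetic expression matrix with planted coexpression modules
#'
#' Latent-factor Gaussian generative model: genes of a module share a
#' standard-normal latent sample profile z, and each gene's values are
#' `sqrt(within_r) * z + sqrt(1 - within_r) * noise`, so every
#' within-module gene pair has expected Pearson correlation `within_r`
#' exactly. Background genes are independent standard-normal noise.
#' Values are on an abundance-like log2 scale.
#'
#' @param n_modules Number of planted modules (0 gives pure noise).
#' @param genes_per_module Genes per module.
#' @param n_background Independent background genes.
#' @param n_samples Number of samples.
#' @param within_r Target within-module Pearson correlation, in (0, 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `matrix` (an [expression_matrix()], scale log2) and
#'   `modules` (named list of gene-id vectors, one per module).
#' @export
make_module_matrix <- function(n_modules, genes_per_module, n_background,
                               n_samples, within_r = 0.9, seed = NULL) {
  if (within_r <= 0 || within_r >= 1)
    stop("'within_r' must lie strictly in (0, 1)")
  if (n_samples < 2L) stop("need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  modules <- list()
  blocks <- list()
  for (j in seq_len(n_modules)) {
    ids <- sprintf("MOD%d_G%03d", j, seq_len(genes_per_module))
    z <- stats::rnorm(n_samples)
    noise <- matrix(stats::rnorm(genes_per_module * n_samples),
                    nrow = genes_per_module)
    block <- sqrt(within_r) * matrix(z, genes_per_module, n_samples,
                                     byrow = TRUE) +
             sqrt(1 - within_r) * noise
    rownames(block) <- ids
    modules[[paste0("MOD", j)]] <- ids
    blocks[[j]] <- block
  }
  if (n_background > 0L) {
    bg <- matrix(stats::rnorm(n_background * n_samples), nrow = n_background,
                 dimnames = list(sprintf("BG_G%04d", seq_len(n_background)),
                                 NULL))
    blocks[[length(blocks) + 1L]] <- bg
  }
  if (!length(blocks)) stop("matrix would have no genes")
  vals <- do.call(rbind, blocks)
  colnames(vals) <- samples
  list(matrix = expression_matrix(vals, "log2"), modules = modules)
}

#' Synthetic grouped samples with tissue-like count distributions
#'
#' Generates a count matrix in which samples cluster by group: every gene
#' has a baseline log2 abundance, each group adds a gene-specific offset of
#' magnitude `shift`, and samples add independent noise; counts are
#' `round(2^value)`. With `shift = 0` the groups are indistinguishable.
#'
#' @param groups Number of sample groups.
#' @param per_group Samples per group.
#' @param n_genes Number of genes.
#' @param shift Standard deviation of the per-gene group offsets (log2
#'   units); sample noise has standard deviation 0.5.
#' @param seed Optional RNG seed.
#' @return A list with `matrix` (an [expression_matrix()], scale counts)
#'   and `meta` (a [sample_metadata()] table; no cell lines).
#' @export
make_grouped_samples <- function(groups, per_group, n_genes = 200,
                                 shift = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- stats::runif(n_genes, 2, 8)
  offset <- matrix(stats::rnorm(n_genes * groups, sd = max(shift, 0)),
                   nrow = n_genes)
  if (shift == 0) offset[] <- 0
  n_s <- groups * per_group
  grp <- rep(seq_len(groups), each = per_group)
  log2val <- base + offset[, grp, drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_s, sd = 0.5), nrow = n_genes)
  counts <- round(2^log2val)
  rownames(counts) <- sprintf("G%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("GRP%d_S%02d", grp,
                              rep(seq_len(per_group), times = groups))
  meta <- sample_metadata(colnames(counts), paste0("group", grp), FALSE)
  list(matrix = expression_matrix(counts, "counts"), meta = meta)
}

#' Term library matched to planted modules
#'
#' Builds one term per planted module (the term's gene set is exactly the
#' module) plus size-matched decoy terms drawn uniformly from the universe.
#'
#' @param modules Named list of gene-id vectors (from
#'   [make_module_matrix()]).
#' @param universe Character vector of all gene ids.
#' @param n_decoys Number of random decoy terms (default: one per module).
#' @param seed Optional RNG seed.
#' @return A [term_library()].
#' @export
make_term_library <- function(modules, universe, n_decoys = length(modules),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  terms <- list()
  for (nm in names(modules)) {
    terms[[paste0("TERM_", nm)]] <-
      list(description = paste("planted module", nm), genes = modules[[nm]])
  }
  sizes <- if (length(modules)) lengths(modules) else 10L
  for (i in seq_len(n_decoys)) {
    sz <- sizes[[((i - 1L) %% length(sizes)) + 1L]]
    terms[[sprintf("DECOY_%02d", i)]] <-
      list(description = "random decoy term",
           genes = sample(universe, min(sz, length(universe))))
  }
  term_library(terms, "synthetic")
}

#' Ultrametric tree with prescribed clade sizes on a driver's ancestor path
#'
#' Builds a binary ultrametric tree in which the driver leaf's successive
#' ancestors subtend exactly the requested numbers of leaves: ancestor i
#' sits at height i and gathers `sizes[i] - sizes[i-1]` additional leaves
#' as a balanced subtree. Useful for exercising clade selection rules on a
#' known geometry.
#'
#' @param sizes Strictly increasing integer vector of clade sizes along the
#'   ancestor path; `sizes[1] >= 2`.
#' @param driver Label for the driver leaf (default "DRV").
#' @return An [ape::phylo] tree with `max(sizes)` leaves.
#' @export
make_ancestor_path_tree <- function(sizes, driver = "DRV") {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || sizes[1L] < 2L || any(diff(sizes) < 1L))
    stop("'sizes' must be strictly increasing with sizes[1] >= 2")
  balanced <- function(labels, h) {
    if (length(labels) == 1L) return(list(str = labels, h = 0))
    half <- ceiling(length(labels) / 2)
    L <- balanced(labels[seq_len(half)], h / 2)
    R <- balanced(labels[-seq_len(half)], h / 2)
    list(str = sprintf("(%s:%.10g,%s:%.10g)",
                       L$str, h - L$h, R$str, h - R$h), h = h)
  }
  total <- max(sizes)
  labels <- sprintf("L%04d", seq_len(total - 1L))
  used <- 0L
  cur <- list(str = driver, h = 0)
  n_leaves <- 1L
  for (i in seq_along(sizes)) {
    h <- i
    add <- sizes[i] - n_leaves
    block <- balanced(labels[used + seq_len(add)], h / 2)
    used <- used + add
    cur <- list(str = sprintf("(%s:%.10g,%s:%.10g)",
                              cur$str, h - cur$h, block$str, h - block$h),
                h = h)
    n_leaves <- sizes[i]
  }
  ape::read.tree(text = paste0(cur$str, ";"))
}
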