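#' Pairwise Pearson correlation matrix over genes or samples
#'
#' @param m An [expression_matrix()].
#' @param axis Compute correlations between `"genes"` (rows) or
#'   `"samples"` (columns).
#' @return A `corr_matrix` object: list with `ids` and the symmetric
#'   correlation matrix `r` (unit diagonal).
#' @export
pearson_matrix <- function(m, axis = c("genes", "samples")) {
  stopifnot(inherits(m, "expr_matrix"))
  axis <- match.arg(axis)
  x <- if (axis == "genes") t(m$values) else m$values
  if (nrow(x) < 2L)
    stop("need at least 2 observations per vector to correlate")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance vector(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " (filter constant genes/samples first)")
  r <- stats::cor(x, method = "pearson")
  diag(r) <- 1
  structure(list(ids = colnames(x), r = r), class = "corr_matrix")
}

#' Transform correlations to distances with d = 1 - r
#'
#' Maps r = 1 (complete correlation) to 0 and r = -1 (complete
#' anti-correlation) to 2. The diagonal is forced to exactly zero and
#' values nudged outside [0, 2] by floating-point error are clamped.
#'
#' @param c A `corr_matrix` from [pearson_matrix()].
#' @return A `dist_matrix` object: list with `ids` and the symmetric
#'   distance matrix `d`.
#' @export
corr_to_distance <- function(c) {
  stopifnot(inherits(c, "corr_matrix"))
  d <- 1 - c$r
  d <- pmin(pmax(d, 0), 2)
  diag(d) <- 0
  dist_matrix(d, c$ids)
}

#' Distance matrix container
#'
#' @param d Symmetric numeric matrix of pairwise distances in [0, 2] with
#'   zero diagonal.
#' @param ids Identifiers for the rows/columns (defaults to the dimnames).
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(d, ids = rownames(d)) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square matrix")
  if (is.null(ids)) stop("distance matrix needs identifiers")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate identifiers in distance matrix")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d ids, range [%.4g, %.4g]\n",
              length(x$ids), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: the pair of clusters with the
#' minimal mean inter-cluster distance is merged repeatedly, at a node of
#' height equal to half that distance, yielding a rooted ultrametric tree.
#' When several cluster pairs tie at the minimal distance, the pair whose
#' (lexicographically smallest leaf) labels sort first is merged, so results
#' are reproducible across platforms. Sibling order in the returned tree is
#' the merge-operand order.
#'
#' @param dm A `dist_matrix` (or plain symmetric matrix with dimnames).
#' @return An ultrametric [ape::phylo] tree whose tips are the matrix ids.
#' @export
upgma <- function(dm) {
  if (!inherits(dm, "dist_matrix")) dm <- dist_matrix(as.matrix(dm))
  n <- length(dm$ids)
  if (n < 2L) stop("need at least 2 ids to build a tree")
  D <- dm$d
  labels <- dm$ids

  size <- rep(1, n)                       # cluster sizes
  node_of <- seq_len(n)                   # phylo node id per active cluster
  rep_label <- labels                     # lexicographic representative
  height <- numeric(2L * n - 1L)          # node heights (tips at 0)
  active <- rep(TRUE, n)
  work <- D
  diag(work) <- Inf

  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  edge_len <- numeric(2L * (n - 1L))
  e <- 0L

  for (merge in seq_len(n - 1L)) {
    # inactive rows/columns hold Inf, so the global minimum is the
    # minimal average inter-cluster distance among active clusters
    mval <- min(work)
    hits <- which(work == mval, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    if (nrow(hits) > 1L) {
      key <- apply(hits, 1L, function(ij) {
        pair <- sort(c(rep_label[ij[1L]], rep_label[ij[2L]]))
        paste(pair, collapse = "\r")
      })
      hits <- hits[order(key), , drop = FALSE]
    }
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    # first operand = lexicographically smaller cluster representative
    if (rep_label[j] < rep_label[i]) { tmp <- i; i <- j; j <- tmp }

    new_node <- n + (n - merge)           # root (last merge) gets id n + 1
    h <- mval / 2
    height[new_node] <- h
    for (child in c(node_of[i], node_of[j])) {
      e <- e + 1L
      edge[e, ] <- c(new_node, child)
      edge_len[e] <- h - height[child]
    }

    # Lance-Williams average-linkage update, stored in slot i
    others <- which(active); others <- others[!others %in% c(i, j)]
    if (length(others)) {
      upd <- (size[i] * work[i, others] + size[j] * work[j, others]) /
             (size[i] + size[j])
      work[i, others] <- upd; work[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    node_of[i] <- new_node
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active[j] <- FALSE
    work[j, ] <- Inf; work[, j] <- Inf
  }

  phy <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = labels, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Heights of all tree nodes above the leaves
#'
#' For an ultrametric tree, a node's height is the root-to-leaf depth minus
#' its depth from the root; the merge height of a UPGMA node is half the
#' average distance between the two clusters it joined.
#'
#' @param phy A rooted tree with edge lengths ([ape::phylo]).
#' @return Numeric vector of heights indexed by phylo node id
#'   (tips `1..n`, then internal nodes).
#' @export
node_heights <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

#' Cophenetic distance matrix implied by a tree
#'
#' Entry (i, j) is the tree path length between leaves i and j — for an
#' ultrametric tree, twice the height of their lowest common ancestor.
#' Comparing it with the original correlation-based distances measures how
#' faithfully the hierarchical clustering represents the data.
#'
#' @param phy A tree with edge lengths ([ape::phylo]).
#' @return A `dist_matrix` over the tree's tip labels, in tip-label order.
#' @export
cophenetic_matrix <- function(phy) {
  cm <- as.matrix(stats::cophenetic(phy))
  cm <- cm[phy$tip.label, phy$tip.label]
  dist_matrix(cm, phy$tip.label)
}

#' Compare original distances with tree cophenetic distances
#'
#' Summarizes, over all leaf pairs (optionally restricted to a subset of
#' ids), the mean original distance, the mean cophenetic distance and their
#' Pearson correlation — a measure of hierarchical-clustering quality.
#'
#' @param dm The original `dist_matrix` the tree was built from.
#' @param phy The tree ([ape::phylo]); its tips must be a subset of
#'   `dm$ids`.
#' @param ids Optional subset of leaf ids to restrict the comparison to.
#' @return A list with `n_pairs`, `mean_original`, `mean_cophenetic` and
#'   `correlation`.
#' @export
distance_fit_summary <- function(dm, phy, ids = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  ids <- if (is.null(ids)) phy$tip.label else intersect(ids, phy$tip.label)
  ids <- intersect(ids, dm$ids)
  if (length(ids) < 2L) stop("need at least 2 shared ids to compare")
  orig <- dm$d[ids, ids]
  coph <- cophenetic_matrix(phy)$d[ids, ids]
  ut <- upper.tri(orig)
  list(n_pairs = sum(ut),
       mean_original = mean(orig[ut]),
       mean_cophenetic = mean(coph[ut]),
       correlation = stats::cor(orig[ut], coph[ut]))
}
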