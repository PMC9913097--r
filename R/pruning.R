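#' Prune a tree to its n most distinct representative leaves
#'
#' Iteratively removes one member of the lowest cherry: among all pairs of
#' leaves sharing a parent, the pair whose parent node is lowest (the two
#' most similar remaining leaves) is located, one of its leaves is deleted
#' and the parent contracted, until `n` leaves remain. Of the two cherry
#' members, the one whose summed cophenetic distance to all other current
#' leaves is smaller is deleted, keeping the more outlying representative;
#' ties (always the case on an exactly ultrametric tree, where cherry
#' members are equidistant from everything else) are broken by deleting the
#' lexicographically larger label. Heights of surviving nodes are never
#' re-estimated, so cophenetic distances among surviving leaves are
#' unchanged.
#'
#' @param phy A rooted tree with edge lengths ([ape::phylo]).
#' @param n Target number of leaves, between 1 and the current leaf count.
#' @return A list with `tree` (the pruned [ape::phylo]) and `pruned`
#'   (ordered character vector of removed leaf labels).
#' @export
prune_to_n <- function(phy, n) {
  n_tips <- length(phy$tip.label)
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > n_tips)
    stop("'n' must be between 1 and the leaf count (", n_tips, ")")
  n <- as.integer(n)
  pruned <- character(0)
  while (length(phy$tip.label) > n) {
    cherry <- lowest_cherry(phy)
    labs <- cherry$labels
    cm <- cophenetic_matrix(phy)$d
    sums <- rowSums(cm[labs, , drop = FALSE])
    # smaller summed distance = more redundant leaf; drop it
    drop_lab <- labs[order(sums, labs, decreasing = c(FALSE, TRUE),
                           method = "radix")[1L]]
    pruned <- c(pruned, drop_lab)
    phy <- drop_one_tip(phy, drop_lab)
  }
  list(tree = phy, pruned = pruned)
}

# Find the cherry (two leaves sharing a parent) with minimal parent height;
# ties broken by the lexicographically smallest sorted label pair.
lowest_cherry <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 2L) stop("tree has no cherry")
  h <- node_heights(phy)
  is_tip_edge <- phy$edge[, 2L] <= nt
  parents <- phy$edge[is_tip_edge, 1L]
  tips <- phy$edge[is_tip_edge, 2L]
  tab <- table(parents)
  cherry_parents <- as.integer(names(tab)[tab == 2L])
  if (!length(cherry_parents)) stop("tree has no cherry")
  ph <- h[cherry_parents]
  cand <- cherry_parents[ph == min(ph)]
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(p) {
      paste(sort(phy$tip.label[tips[parents == p]]), collapse = "\r")
    }, character(1L))
    cand <- cand[order(keys)]
  }
  p <- cand[1L]
  list(parent = p, labels = sort(phy$tip.label[tips[parents == p]]),
       height = h[p])
}

# drop.tip cannot produce a single-leaf tree; build it by hand when needed
drop_one_tip <- function(phy, label) {
  if (length(phy$tip.label) == 2L) {
    keep <- setdiff(phy$tip.label, label)
    structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                   edge.length = max(node_heights(phy)),
                   tip.label = keep, Nnode = 1L),
              class = "phylo", order = "cladewise")
  } else {
    ape::drop.tip(phy, label)
  }
}
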