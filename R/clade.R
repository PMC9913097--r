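#' Ancestor path of a driver-gene leaf
#'
#' Walks from the driver leaf towards the root and reports, for each
#' internal-node count k (1 = parent), the ancestor node and the number of
#' leaves its clade subtends.
#'
#' @param phy A rooted [ape::phylo] tree.
#' @param driver A tip label of `phy`.
#' @return A data frame with columns `k`, `node` and `size`.
#' @export
ancestor_path <- function(phy, driver) {
  tip <- find_driver_tip(phy, driver)
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  n_below <- ape::node.depth(phy)   # number of descendant tips per node
  nodes <- integer(0)
  cur <- tip
  while (parent[cur] != 0L) {
    cur <- parent[cur]
    nodes <- c(nodes, cur)
  }
  data.frame(k = seq_along(nodes), node = nodes, size = n_below[nodes])
}

find_driver_tip <- function(phy, driver) {
  tip <- match(driver, phy$tip.label)
  if (is.na(tip)) {
    near <- utils::head(c(
      phy$tip.label[strip_gene_version(phy$tip.label) ==
                      strip_gene_version(driver)],
      phy$tip.label[agrepl(driver, phy$tip.label, max.distance = 0.2)]), 5L)
    stop("driver gene '", driver, "' is not a leaf of the tree",
         if (length(near)) paste0("; near matches: ",
                                  paste(unique(near), collapse = ", ")))
  }
  tip
}

#' Maximum allowed clade size for a tree
#'
#' The clade around a driver gene may grow up to 25% of all genes studied;
#' the cap is `ceiling(cap_fraction * leaf count)`, so equality is allowed.
#'
#' @param phy The full tree.
#' @param cap_fraction Fraction of leaves allowed in one clade
#'   (default 0.25).
#' @return Integer leaf-count cap.
#' @export
clade_size_cap <- function(phy, cap_fraction = 0.25) {
  as.integer(ceiling(cap_fraction * length(phy$tip.label)))
}

#' Extract the coexpression clade k internal nodes above a driver gene
#'
#' Returns the subtree rooted at the k-th ancestor of the driver leaf
#' (ancestor 1 = its parent). If that clade would exceed the size cap
#' (25% of all leaves by default), the largest smaller k whose clade
#' respects the cap is used instead and the result is flagged as capped.
#' Requests beyond the driver's ancestor depth are clamped to the root.
#'
#' @param phy The full coexpression tree ([ape::phylo]).
#' @param driver A tip label: the driver gene.
#' @param k Number of internal nodes from the driver leaf to the clade root.
#' @param cap_fraction Fraction of leaves allowed in one clade
#'   (default 0.25).
#' @return A `coex_clade` object: list with `driver`, `internal_nodes`
#'   (effective k), `requested_nodes`, `capped`, `root_node`, `size`,
#'   `tree` (the clade as [ape::phylo]) and `gene_ids`.
#' @export
clade_at <- function(phy, driver, k, cap_fraction = 0.25) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stop("'k' must be a single integer >= 1")
  path <- ancestor_path(phy, driver)
  k_req <- as.integer(k)
  k_eff <- min(k_req, nrow(path))
  cap <- clade_size_cap(phy, cap_fraction)
  ok <- which(path$size[seq_len(k_eff)] <= cap)
  if (!length(ok))
    stop("even the parent clade of '", driver, "' exceeds the size cap (",
         cap, " leaves); the tree is too small for a capped clade")
  capped <- max(ok) < k_eff
  k_eff <- max(ok)
  new_clade(phy, driver, path$node[k_eff], k_eff, k_req, capped)
}

new_clade <- function(phy, driver, node, k_eff, k_req, capped) {
  sub <- if (node == length(phy$tip.label) + 1L) phy
         else ape::extract.clade(phy, node)
  structure(list(driver = driver,
                 internal_nodes = k_eff,
                 requested_nodes = k_req,
                 capped = capped,
                 root_node = node,
                 size = length(sub$tip.label),
                 tree = sub,
                 gene_ids = sub$tip.label),
            class = "coex_clade")
}

#' @export
print.coex_clade <- function(x, ...) {
  cat(sprintf("coex_clade: driver %s, %d internal node(s), %d gene(s)%s\n",
              x$driver, x$internal_nodes, x$size,
              if (x$capped) " [capped]" else ""))
  invisible(x)
}

#' Default coexpression clade: the ancestor clade closest to a target size
#'
#' Scans the driver's ancestor path and returns the clade whose leaf count
#' is closest to `target` (25 genes by default). Ties are resolved towards
#' the smaller clade. The 25% size cap restricts the candidates only when
#' the capped maximum is at least `target`; on small trees, where even a
#' quarter of the leaves could not hold the target, the full ancestor path
#' is eligible.
#'
#' @inheritParams clade_at
#' @param target Ideal clade size in genes (default 25).
#' @return A `coex_clade` object (see [clade_at()]).
#' @export
default_clade <- function(phy, driver, target = 25, cap_fraction = 0.25) {
  path <- ancestor_path(phy, driver)
  cap <- clade_size_cap(phy, cap_fraction)
  cand <- if (cap >= target) path[path$size <= cap, , drop = FALSE] else path
  if (!nrow(cand)) cand <- path[1L, , drop = FALSE]
  best <- cand[order(abs(cand$size - target), cand$size), , drop = FALSE][1L, ]
  new_clade(phy, driver, best$node, best$k, best$k,
            capped = best$size > cap)
}

#' Gene list of a clade
#'
#' @param clade A `coex_clade`.
#' @param annotations Optional gene descriptions: a named character vector,
#'   or a data frame with columns `gene_id` and `description`. Matching is
#'   on stable ids (versions stripped).
#' @return A data frame with columns `gene_id` and `description`, in the
#'   clade's leaf traversal order.
#' @export
clade_gene_list <- function(clade, annotations = NULL) {
  stopifnot(inherits(clade, "coex_clade"))
  ids <- clade$gene_ids
  desc <- rep(NA_character_, length(ids))
  if (!is.null(annotations)) {
    if (is.data.frame(annotations)) {
      ann <- stats::setNames(as.character(annotations$description),
                             annotations$gene_id)
    } else ann <- annotations
    names(ann) <- strip_gene_version(names(ann))
    hit <- match(strip_gene_version(ids), names(ann))
    desc[!is.na(hit)] <- ann[hit[!is.na(hit)]]
  }
  data.frame(gene_id = ids, description = desc, stringsAsFactors = FALSE)
}

#' Newick serialization of a clade subtree
#'
#' @param clade A `coex_clade`.
#' @return A single Newick string preserving the subtree branch lengths.
#' @export
clade_newick <- function(clade) {
  stopifnot(inherits(clade, "coex_clade"))
  ape::write.tree(clade$tree)
}
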