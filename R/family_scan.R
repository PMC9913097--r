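#' Locate concentrations of a gene family across the coexpression tree
#'
#' Scans every internal-node clade of at least `min_size` leaves, counts
#' family members per clade, and reports maximal disjoint clades ranked by
#' family count: candidates are visited in order of decreasing count
#' (smaller clades first at equal count, so a tight family clade beats the
#' enclosing tree), and a clade overlapping an already-reported clade is
#' suppressed. Family ids are matched on stable ids (versions stripped).
#'
#' @param phy The coexpression tree ([ape::phylo]).
#' @param family Character vector of family gene ids; must share at least
#'   one member with the tree's leaves.
#' @param min_size Smallest clade size scanned (default 2).
#' @return A data frame with columns `node` (internal phylo node id),
#'   `size`, `family_count` and `family_fraction`, ranked by family count.
#' @export
family_clade_scan <- function(phy, family, min_size = 2) {
  family <- unique(strip_gene_version(as.character(family)))
  tips_stable <- strip_gene_version(phy$tip.label)
  in_family <- tips_stable %in% family
  if (!any(in_family))
    stop("no family member is a leaf of the tree")
  nt <- length(phy$tip.label)
  parts <- ape::prop.part(phy)   # tip sets per internal node, root first
  size <- lengths(parts)
  count <- vapply(parts, function(tips) sum(in_family[tips]), integer(1L))
  keep <- which(size >= min_size & count > 0L)
  if (!length(keep)) {
    return(data.frame(node = integer(), size = integer(),
                      family_count = integer(), family_fraction = numeric()))
  }
  ord <- keep[order(-count[keep], size[keep], keep)]
  reported <- integer(0)
  covered <- logical(nt)
  for (i in ord) {
    tips <- parts[[i]]
    if (!any(covered[tips])) {
      reported <- c(reported, i)
      covered[tips] <- TRUE
    }
  }
  data.frame(node = reported + nt,   # prop.part index 1 = root node nt + 1
             size = size[reported],
             family_count = count[reported],
             family_fraction = count[reported] / size[reported])
}
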