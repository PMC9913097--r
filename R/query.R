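#' Enrichment category keywords
#'
#' Two-character keywords selecting an enrichment category in [run_query()]:
#' `bp`/`mf`/`cc` (Gene Ontology aspects), `ke` (KEGG-style pathways),
#' `wi` (WikiPathways-style pathways), `tf` (transcription-factor targets),
#' `di` (gene-disease associations), `pf` (protein families/domains),
#' `cb` (chromosome bands).
#'
#' @return Named character vector mapping keyword to category description.
#' @export
enrichment_categories <- function() {
  c(bp = "Gene Ontology: Biological Process",
    mf = "Gene Ontology: Molecular Function",
    cc = "Gene Ontology: Cellular Component",
    ke = "Biological pathways (KEGG-style)",
    wi = "Biological pathways (WikiPathways-style)",
    tf = "Transcription factor targets",
    di = "Gene-disease associations",
    pf = "Protein families and domains",
    cb = "Chromosome bands")
}

#' Run a driver-gene coexpression query
#'
#' The programmatic counterpart of a webtool/API query keyed on a driver
#' gene id, an internal-node count, and an optional two-character
#' enrichment-category keyword. Returns a JSON-ready document containing
#' the driver details, the clade in Newick form, the clade gene list, and
#' — when a recognized keyword names a loaded library — the enrichment
#' rows ranked by p-value ascending. An unrecognized (or missing) keyword
#' yields a document without an enrichment block, not an error; an unknown
#' driver yields a structured error document.
#'
#' @param phy The gene coexpression tree ([ape::phylo]).
#' @param driver Driver gene id (a tip label).
#' @param k Internal-node count for [clade_at()].
#' @param keyword Optional 2-character category keyword (see
#'   [enrichment_categories()]).
#' @param libraries Named list of [term_library()] objects keyed by
#'   category keyword.
#' @param universe Gene universe for enrichment; defaults to all tree
#'   leaves (stable ids).
#' @param annotations Optional gene descriptions (see
#'   [clade_gene_list()]).
#' @param alpha FDR threshold passed to [enrich()].
#' @return A nested list (the query document); serialize with
#'   [query_to_json()].
#' @export
run_query <- function(phy, driver, k, keyword = NULL, libraries = list(),
                      universe = NULL, annotations = NULL, alpha = 0.05) {
  if (!driver %in% phy$tip.label) {
    near <- phy$tip.label[strip_gene_version(phy$tip.label) ==
                            strip_gene_version(driver)]
    return(list(error = list(
      code = "unknown_driver",
      message = paste0("driver gene '", driver, "' is not in the tree"),
      near_matches = as.list(near))))
  }
  clade <- clade_at(phy, driver, k)
  genes <- clade_gene_list(clade, annotations)
  doc <- list(
    query = list(driver = driver, internal_nodes = as.integer(k),
                 category = if (is.null(keyword)) NA_character_ else keyword),
    driver = list(gene_id = driver,
                  description = genes$description[genes$gene_id == driver]),
    clade = list(internal_nodes = clade$internal_nodes,
                 requested_nodes = clade$requested_nodes,
                 capped = clade$capped,
                 size = clade$size,
                 newick = clade_newick(clade),
                 genes = genes))
  if (!is.null(keyword) && keyword %in% names(enrichment_categories()) &&
      keyword %in% names(libraries)) {
    if (is.null(universe)) universe <- strip_gene_version(phy$tip.label)
    res <- enrich(clade$gene_ids, libraries[[keyword]], universe, alpha)
    doc$enrichment <- list(category = unname(enrichment_categories()[keyword]),
                           n_tested = attr(res, "n_tested"),
                           terms = res)
  }
  doc
}

#' Serialize a query document to JSON
#'
#' @param doc A document from [run_query()].
#' @return A JSON string.
#' @export
query_to_json <- function(doc) {
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                   na = "null", pretty = TRUE)
}

#' Validate the structure of a query document
#'
#' Checks a [run_query()] result against the shipped result schema
#' (`inst/schema/query_result.schema.json`): required blocks and field
#' types for either a successful document or a structured error.
#'
#' @param doc A document from [run_query()].
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_query_document <- function(doc) {
  if (!is.null(doc$error)) {
    need <- c("code", "message")
    miss <- setdiff(need, names(doc$error))
    if (length(miss))
      stop("error document missing field(s): ", paste(miss, collapse = ", "))
    return(invisible(TRUE))
  }
  for (blk in c("query", "driver", "clade")) {
    if (is.null(doc[[blk]])) stop("document missing block '", blk, "'")
  }
  need <- c("internal_nodes", "capped", "size", "newick", "genes")
  miss <- setdiff(need, names(doc$clade))
  if (length(miss))
    stop("clade block missing field(s): ", paste(miss, collapse = ", "))
  if (!is.character(doc$clade$newick))
    stop("clade newick must be a string")
  phy <- ape::read.tree(text = doc$clade$newick)
  if (is.null(phy)) stop("clade newick does not parse")
  if (length(phy$tip.label) != doc$clade$size)
    stop("clade size does not match its newick leaf count")
  if (!is.null(doc$enrichment)) {
    if (is.null(doc$enrichment$terms))
      stop("enrichment block missing 'terms'")
    p <- doc$enrichment$terms$p
    if (length(p) > 1L && is.unsorted(p))
      stop("enrichment terms must be ranked by p ascending")
  }
  invisible(TRUE)
}

#' Preprocess an expression matrix for tree building
#'
#' Applies, in order: gene-id filters (suffix and deprecated ids),
#' zero-standard-deviation gene removal (on `detect` when a companion
#' abundance matrix such as TPM is supplied, otherwise on `m` itself),
#' cell-line sample removal, smoothed quantile normalization (when
#' metadata with at least one group is given and `m` is on the counts
#' scale), and finally the zero-replacement log2 transform.
#'
#' @param m The matrix to normalize and transform (typically counts).
#' @param detect Optional companion [expression_matrix()] (typically TPM)
#'   on which non-expressed / constant genes are detected; must contain
#'   every gene of `m`.
#' @param meta Optional [sample_metadata()]; enables cell-line removal and
#'   group-aware normalization.
#' @param suffix Gene-id suffix to drop (default `"_PAR_Y"`).
#' @param deprecated Deprecated stable gene ids to drop.
#' @param normalize Run [qsmooth_normalize()] (default `TRUE` when `meta`
#'   is given).
#' @param log2_transform Apply [replace_zeros_and_log2()] at the end
#'   (default `TRUE`).
#' @return A list with `matrix` (the processed `expr_matrix`) and
#'   `reports` (list of `filter_report`s).
#' @export
preprocess_expression <- function(m, detect = NULL, meta = NULL,
                                  suffix = "_PAR_Y",
                                  deprecated = character(),
                                  normalize = !is.null(meta),
                                  log2_transform = TRUE) {
  reports <- list()
  f <- filter_gene_ids(m, suffix, deprecated)
  reports$gene_ids <- f$report
  m <- f$matrix
  sd_source <- if (is.null(detect)) m else {
    miss <- setdiff(gene_ids(m), gene_ids(detect))
    if (length(miss))
      stop("detect matrix is missing gene(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    expression_matrix(detect$values[gene_ids(m), , drop = FALSE],
                      detect$scale)
  }
  z <- filter_zero_sd_genes(sd_source)
  reports$zero_sd <- z$report
  keep <- setdiff(gene_ids(m), z$report$removed_zero_sd)
  m <- expression_matrix(m$values[keep, , drop = FALSE], m$scale)
  if (!is.null(meta)) {
    cl <- drop_cell_line_samples(m, meta)
    reports$cell_line <- cl$report
    m <- cl$matrix
  }
  if (normalize) {
    if (is.null(meta)) stop("normalization requires sample metadata")
    m <- qsmooth_normalize(m, meta)
  }
  if (log2_transform && m$scale != "log2") m <- replace_zeros_and_log2(m)
  list(matrix = m, reports = reports)
}

#' Build a gene (or sample) coexpression tree from an expression matrix
#'
#' Convenience chain: Pearson correlation, d = 1 - r, UPGMA.
#'
#' @param m An [expression_matrix()] (normalized/log2 for genes).
#' @param axis `"genes"` or `"samples"`.
#' @return An ultrametric [ape::phylo] coexpression tree.
#' @export
build_coexpression_tree <- function(m, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  upgma(corr_to_distance(pearson_matrix(m, axis)))
}
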