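#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x samples matrix carrying a value
#' scale tag. Row names are gene identifiers, column names sample
#' identifiers; both must be unique and all values finite. Values on the
#' `counts` or `tpm` scale must be non-negative.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   row and column names set.
#' @param scale Value scale, one of `"counts"`, `"tpm"` or `"log2"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values, scale = c("counts", "tpm", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("'values' must have gene row names")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("'values' must have sample column names")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (length(values) && any(!is.finite(values)))
    stop("all expression values must be finite")
  if (scale %in% c("counts", "tpm") && length(values) && any(values < 0))
    stop("negative values are not allowed on the '", scale, "' scale")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of sample identifiers and one row per gene with the
#' gene identifier in the first column. An optional two-line GCT preamble
#' (`#1.2` followed by a dimensions line) is detected and skipped, as is a
#' GCT `Description` column.
#'
#' @param path Path to the tab-separated file.
#' @param scale Declared value scale of the file contents.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, scale = c("counts", "tpm", "log2")) {
  scale <- match.arg(scale)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("^#1\\.2", first)) 2L else 0L
  df <- utils::read.delim(path, header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 1L) stop("no columns found in ", path)
  ids <- df[[1L]]
  body_cols <- seq(2L, length.out = ncol(df) - 1L)
  # GCT files carry a Description column right after the gene id
  if (length(body_cols) && tolower(names(df)[2L]) == "description")
    body_cols <- body_cols[-1L]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(body_cols),
                 dimnames = list(ids, names(df)[body_cols]))
  for (j in seq_along(body_cols)) {
    col <- df[[body_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], ids[bad[1L]], names(df)[body_cols[j]]))
    vals[, j] <- num
  }
  expression_matrix(vals, scale)
}

#' Read a sample metadata table
#'
#' Tab-separated file with columns `sample_id`, `group` and `is_cell_line`
#' (0/1 or true/false).
#'
#' @param path Path to the metadata file.
#' @return A data frame with columns `sample_id`, `group`, `is_cell_line`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "is_cell_line")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "))
  sample_metadata(df$sample_id, df$group, df$is_cell_line)
}

#' Construct a sample metadata table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Tissue/group label per sample; must be non-empty strings.
#' @param is_cell_line Logical (or 0/1, "true"/"false") flag per sample.
#' @return A data frame with columns `sample_id`, `group`, `is_cell_line`.
#' @export
sample_metadata <- function(sample_id, group, is_cell_line = FALSE) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  n <- length(sample_id)
  is_cell_line <- rep_len(is_cell_line, n)
  if (is.character(is_cell_line))
    is_cell_line <- tolower(is_cell_line) %in% c("1", "true", "t", "yes")
  is_cell_line <- as.logical(is_cell_line)
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  if (length(group) != n)
    stop("'group' must have one label per sample")
  if (any(is.na(group) | !nzchar(group)))
    stop("every sample needs a non-empty group label")
  if (any(is.na(is_cell_line)))
    stop("'is_cell_line' must be interpretable as logical")
  data.frame(sample_id = sample_id, group = group,
             is_cell_line = is_cell_line, stringsAsFactors = FALSE)
}

#' Replace zeros with the minimum non-zero value and log2-transform
#'
#' Every zero is replaced by the single smallest non-zero value found
#' anywhere in the matrix, after which all values are log2-transformed.
#' This makes a TPM matrix safe to log-transform without discarding
#' non-expressed entries.
#'
#' @param m An [expression_matrix()] on the `tpm` (or `counts`) scale.
#' @return An `expr_matrix` on the `log2` scale.
#' @examples
#' m <- expression_matrix(matrix(c(0, 2, 8, 4, 0, 1), nrow = 3,
#'   dimnames = list(paste0("G", 1:3), c("S1", "S2"))), "tpm")
#' replace_zeros_and_log2(m)$values
#' @export
replace_zeros_and_log2 <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "log2")
    stop("matrix is already on the log2 scale")
  v <- m$values
  pos <- v[v > 0]
  if (!length(pos))
    stop("matrix has no non-zero values; cannot log2-transform")
  v[v == 0] <- min(pos)
  expression_matrix(log2(v), "log2")
}

filter_report <- function(removed_zero_sd = character(),
                          removed_suffix = character(),
                          removed_deprecated = character(),
                          removed_cell_line_samples = character()) {
  structure(list(removed_zero_sd = removed_zero_sd,
                 removed_suffix = removed_suffix,
                 removed_deprecated = removed_deprecated,
                 removed_cell_line_samples = removed_cell_line_samples),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d zero-SD, %d suffix, %d deprecated ",
                     "genes; %d cell-line samples removed\n"),
              length(x$removed_zero_sd), length(x$removed_suffix),
              length(x$removed_deprecated),
              length(x$removed_cell_line_samples)))
  invisible(x)
}

#' Remove genes with zero standard deviation across samples
#'
#' A gene is removed when its values are exactly constant across all
#' samples (max equals min), the literal zero-standard-deviation criterion.
#' Retained genes keep their input order.
#'
#' @param m An [expression_matrix()].
#' @return A list with elements `matrix` (the filtered `expr_matrix`) and
#'   `report` (a `filter_report` listing removed gene ids).
#' @export
filter_zero_sd_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) == 0L)
    stop("matrix has no genes")
  v <- m$values
  if (ncol(v) == 0L)
    stop("matrix has no samples")
  constant <- apply(v, 1L, function(r) max(r) == min(r))
  removed <- rownames(v)[constant]
  list(matrix = expression_matrix(v[!constant, , drop = FALSE], m$scale),
       report = filter_report(removed_zero_sd = removed))
}

#' Remove genes by identifier suffix or deprecated-id membership
#'
#' Drops genes whose (versioned) identifier ends with `suffix` — e.g. the
#' `_PAR_Y` pseudoautosomal duplicates — and genes whose stable identifier
#' (the id truncated at the first dot) appears in `deprecated`.
#'
#' @param m An [expression_matrix()].
#' @param suffix Suffix string to match at the end of the versioned id;
#'   `NULL` or `""` disables the suffix rule.
#' @param deprecated Character vector of deprecated stable gene ids.
#' @return A list with elements `matrix` and `report` as in
#'   [filter_zero_sd_genes()].
#' @export
filter_gene_ids <- function(m, suffix = "_PAR_Y", deprecated = character()) {
  stopifnot(inherits(m, "expr_matrix"))
  ids <- rownames(m$values)
  by_suffix <- if (is.null(suffix) || !nzchar(suffix)) rep(FALSE, length(ids))
               else endsWith(ids, suffix)
  stable <- strip_gene_version(ids)
  by_depr <- stable %in% strip_gene_version(deprecated) & !by_suffix
  keep <- !(by_suffix | by_depr)
  list(matrix = expression_matrix(m$values[keep, , drop = FALSE], m$scale),
       report = filter_report(removed_suffix = ids[by_suffix],
                              removed_deprecated = ids[by_depr]))
}

#' Remove cell-line samples using the metadata table
#'
#' @param m An [expression_matrix()].
#' @param meta A metadata data frame from [sample_metadata()]; every sample
#'   of `m` must be present.
#' @return A list with elements `matrix` and `report`.
#' @export
drop_cell_line_samples <- function(m, meta) {
  stopifnot(inherits(m, "expr_matrix"))
  ids <- colnames(m$values)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  flag <- meta$is_cell_line[match(ids, meta$sample_id)]
  list(matrix = expression_matrix(m$values[, !flag, drop = FALSE], m$scale),
       report = filter_report(removed_cell_line_samples = ids[flag]))
}

#' Truncate versioned gene identifiers to stable ids
#'
#' @param ids Character vector of gene identifiers, possibly with a
#'   `.version` suffix.
#' @return The identifiers truncated at the first dot.
#' @export
strip_gene_version <- function(ids) sub("\\..*$", "", ids)
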