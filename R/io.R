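#' Write a distance matrix in square PHYLIP format
#'
#' First line is the taxon count; each following line holds a name and the
#' full row of distances (relaxed PHYLIP: names are whitespace-delimited
#' rather than fixed-width). Names containing whitespace are sanitized by
#' replacing runs of whitespace with `_`; a warning reports the mapping.
#'
#' @param dm A `dist_matrix`.
#' @param path Output file path.
#' @param digits Significant digits written (default 10).
#' @return Invisibly, a data frame mapping original to written names.
#' @export
write_phylip <- function(dm, path, digits = 10) {
  stopifnot(inherits(dm, "dist_matrix"))
  ids <- dm$ids
  clean <- gsub("[[:space:]]+", "_", ids)
  if (any(clean != ids)) {
    warning("sanitized ", sum(clean != ids), " name(s) containing whitespace")
  }
  if (anyDuplicated(clean))
    stop("name sanitization produced duplicate ids; rename inputs")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", length(ids)), con)
  for (i in seq_along(ids)) {
    row <- format(dm$d[i, ], digits = digits, scientific = FALSE, trim = TRUE)
    writeLines(paste(c(clean[i], row), collapse = "  "), con)
  }
  invisible(data.frame(original = ids, written = clean,
                       stringsAsFactors = FALSE))
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to a square (relaxed) PHYLIP distance-matrix file.
#' @return A `dist_matrix`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("first line of ", path, " must be the taxon count")
  if (length(lines) - 1L != n)
    stop(sprintf("taxon count %d does not match %d data row(s) in %s",
                 n, length(lines) - 1L, path))
  ids <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != n + 1L)
      stop(sprintf("row %d of %s has %d fields; expected name + %d distances",
                   i, path, length(parts), n))
    ids[i] <- parts[1L]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric distance in row %d of %s", i, path))
    d[i, ] <- vals
  }
  dist_matrix(d, ids)
}

#' Write a tree in Newick format
#'
#' Labels containing Newick-special characters are single-quoted on output.
#'
#' @param phy An [ape::phylo] tree.
#' @param path Output file path.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("failed to parse Newick file ",
                                           path, ": ", conditionMessage(e)))
  if (is.null(phy)) stop("failed to parse Newick file ", path)
  phy
}

#' Read a GMT term library
#'
#' One line per term: term id, description, then member gene ids, all
#' tab-separated. Versioned gene ids are truncated to stable ids.
#'
#' @param path Path to the GMT file.
#' @param category Optional category label stored with the library.
#' @return A `term_library` object (see [term_library()]).
#' @export
read_gmt <- function(path, category = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields in ", path)
    list(description = parts[2L],
         genes = unique(strip_gene_version(parts[-(1:2)])))
  })
  names(terms) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  term_library(terms, category)
}

#' Write a term library in GMT format
#'
#' @param lib A `term_library`.
#' @param path Output file path.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "term_library"))
  lines <- vapply(names(lib$terms), function(id) {
    t <- lib$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
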