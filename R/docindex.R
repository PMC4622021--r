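#' Document indexes
#'
#' A document index maps a normalized term to the list of PMIDs of documents
#' mentioning it, emulating per-term PMC E-utilities queries offline.  Each
#' term's list is deduplicated and truncated to the retrieval cap (default
#' 10,000 PMIDs per term, the `retmax` used for live queries); note that a
#' disorder whose synonyms are unified downstream can still accumulate more
#' than the cap across its synonym lists.
#'
#' @param terms Character vector of terms.
#' @param pmid_lists List of character PMID vectors, parallel to `terms`.
#' @param cap Per-term retrieval cap.
#' @return An object of class `pm_docindex`.
#' @export
document_index <- function(terms = character(0), pmid_lists = list(),
                           cap = 10000L) {
  stopifnot(length(terms) == length(pmid_lists), cap >= 1L)
  lists <- lapply(pmid_lists, function(p) {
    p <- unique(as.character(p))
    if (length(p) > cap) p <- p[seq_len(cap)]
    p
  })
  structure(list(terms = stats::setNames(lists, tolower(terms)), cap = cap),
            class = "pm_docindex")
}

#' @export
print.pm_docindex <- function(x, ...) {
  cat(sprintf("<pm_docindex: %d terms, cap %d>\n", length(x$terms), x$cap))
  invisible(x)
}

index_lookup <- function(index, term) {
  hits <- index$terms[[tolower(term)]]
  if (is.null(hits)) character(0) else hits
}

index_terms <- function(index) names(index$terms)

#' Read / write the document-index TSV format
#'
#' Two tab-separated columns: term, comma-separated PMID list.  Files ending
#' in `.gz` are read/written compressed.
#'
#' @param path File path.
#' @param cap Per-term retrieval cap applied on load.
#' @return `read_document_index` returns a [document_index()];
#'   `write_document_index` returns `path` invisibly.
#' @export
read_document_index <- function(path, cap = 10000L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  lists <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2])) character(0)
    else strsplit(p[2], ",", fixed = TRUE)[[1]]
  })
  document_index(terms, lists, cap = cap)
}

#' @rdname read_document_index
#' @param index A [document_index()].
#' @export
write_document_index <- function(index, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(vapply(seq_along(index$terms), function(i) {
    paste0(names(index$terms)[i], "\t", paste(index$terms[[i]], collapse = ","))
  }, character(1)), con)
  invisible(path)
}
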