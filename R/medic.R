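#' Disorder vocabularies
#'
#' A disorder vocabulary lists Mendelian disorders with a canonical name, an
#' OMIM identifier and synonyms.  The expected source is a MEDIC-style TSV
#' (the merged disease vocabulary unifying OMIM with the MeSH disease
#' subtree): columns `DiseaseName`, `DiseaseID`, `AltDiseaseIDs`,
#' `Synonyms` (pipe-separated).  Only rows carrying an OMIM identifier --
#' either as the DiseaseID or among the alternative IDs -- are kept, since
#' the mined rules target OMIM disorders.
#'
#' @param canonical_name Character vector of unique disorder names.
#' @param omim_id OMIM identifiers (`OMIM:` prefix optional).
#' @param synonyms List of character synonym vectors (may be empty vectors).
#' @return An object of class `pm_disorders` (data frame with a `synonyms`
#'   list column).
#' @export
disorder_vocabulary <- function(canonical_name, omim_id, synonyms = NULL) {
  stopifnot(!anyDuplicated(canonical_name), all(nzchar(omim_id)))
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), length(canonical_name))
  stopifnot(length(synonyms) == length(canonical_name))
  for (s in synonyms) stopifnot(all(nzchar(s)))
  df <- data.frame(canonical_name = as.character(canonical_name),
                   omim_id = as.character(omim_id),
                   stringsAsFactors = FALSE)
  df$synonyms <- synonyms
  class(df) <- c("pm_disorders", "data.frame")
  df
}

#' @export
print.pm_disorders <- function(x, ...) {
  cat(sprintf("<pm_disorders: %d disorders>\n", nrow(x)))
  invisible(x)
}

#' Load a MEDIC-style disorder vocabulary
#'
#' Skips `#` comment lines.  Rows without any OMIM identifier are dropped;
#' when several OMIM IDs are present the first is kept.
#'
#' @param path TSV file with columns DiseaseName, DiseaseID, AltDiseaseIDs,
#'   Synonyms (pipe-separated; the last two may be empty).
#' @return A [disorder_vocabulary()].
#' @export
read_medic <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^DiseaseName\t", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  name <- character(0); omim <- character(0); syns <- list()
  for (p in parts) {
    if (length(p) < 2L) stop("malformed MEDIC row: ", paste(p, collapse = "\t"))
    ids <- c(p[2], if (length(p) >= 3L && nzchar(p[3]))
      strsplit(p[3], "|", fixed = TRUE)[[1]] else character(0))
    omim_ids <- grep("^OMIM:", ids, value = TRUE)
    if (length(omim_ids) == 0L) next
    name <- c(name, p[1])
    omim <- c(omim, omim_ids[1])
    syn <- if (length(p) >= 4L && nzchar(p[4]))
      strsplit(p[4], "|", fixed = TRUE)[[1]] else character(0)
    syns[[length(syns) + 1L]] <- syn
  }
  disorder_vocabulary(name, omim, syns)
}
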