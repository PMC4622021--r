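ENTITY_NAMESPACES <- c("FMA", "RXNORM", "CHEBI", "MA", "MP", "HP",
                       "DOID", "ORDO", "OMIM")
QUALITY_NAMESPACES <- "PATO"

#' Normalize a phenotype surface form
#'
#' Lowercases, strips leading determiners (a, an, the) and collapses internal
#' whitespace.  Used for corpus-wide deduplication and document-index lookup;
#' the stored surface form keeps its determiners.  Idempotent.
#'
#' @param surface Character vector of surface phrases.
#' @return Normalized character vector.
#' @export
normalize_term <- function(surface) {
  stopifnot(all(nzchar(surface)))
  x <- tolower(trimws(surface))
  x <- gsub("[[:space:]]+", " ", x)
  # strip repeatedly so stacked determiners cannot survive one pass
  x <- sub("^((a|an|the) )+", "", x)
  x
}

# concept tags (NAMESPACE:ID strings) found in SEM leaves of a subtree
sem_concepts <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (node$label == "SEM" && length(node$children) == 1L) {
      out <<- c(out, strsplit(node$children[[1]]$label, ";", fixed = TRUE)[[1]])
      return(invisible())
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  unique(out)
}

concept_namespace <- function(tags) sub(":.*$", "", tags)

#' Extract phenotype candidates from annotated sentences
#'
#' Runs every pattern over every annotated tree; each distinct matched root
#' becomes one raw candidate whose surface form is the word yield of the root
#' subtree (SEM leaves excluded).  Candidates are deduplicated corpus-wide on
#' the normalized surface form, merging provenance and concept links, and
#' assigned accessions `PM1`, `PM2`, ... in first-occurrence order.
#'
#' Quality concepts are the PATO hits inside the matched subtree; entity
#' concepts are hits from the entity namespaces (FMA, RxNORM, ChEBI, MA, MP,
#' HP, DOID, ORDO, OMIM).  Every extracted candidate has at least one of
#' each, because every pattern requires a PATO node and an entity node (the
#' EQ completeness property).
#'
#' @param sentences Sentence data frame whose `ptb_tree` column carries SEM
#'   annotations (see [annotate_sentences()]).
#' @param patterns Named list of `pm_pattern` objects (default the nine
#'   built-in patterns).
#' @return A `pm_candidates` data frame with columns `pm_id`, `surface`,
#'   `normalized`, `df` (NA until [filter_by_df()]), and list columns
#'   `qualities`, `entities`, `sources` (data frame of pmid, sent_index,
#'   pattern_id rows), `df_pmids`.
#' @export
extract_candidates <- function(sentences, patterns = builtin_patterns()) {
  bucket <- list()   # normalized -> candidate accumulator
  order_seen <- character(0)
  for (i in seq_len(nrow(sentences))) {
    tree <- read_ptb(sentences$ptb_tree[i])
    seen_roots <- list()
    for (pid in names(patterns)) {
      ms <- match_pattern(patterns[[pid]], tree)
      roots <- unique(vapply(ms, `[[`, integer(1), "root"))
      for (r in roots) {
        key <- as.character(r)
        sub <- seen_roots[[key]]
        if (is.null(sub)) {
          sub <- subtree_at(tree, r)
          seen_roots[[key]] <- sub
        }
        surface <- paste(tree_yield(sub), collapse = " ")
        norm <- normalize_term(surface)
        tags <- sem_concepts(sub)
        ns <- concept_namespace(tags)
        qual <- tags[ns %in% QUALITY_NAMESPACES]
        ent <- tags[ns %in% ENTITY_NAMESPACES]
        cand <- bucket[[norm]]
        if (is.null(cand)) {
          cand <- list(surface = surface, normalized = norm,
                       qualities = character(0), entities = character(0),
                       sources = list())
          order_seen <- c(order_seen, norm)
        }
        cand$qualities <- sort(unique(c(cand$qualities, qual)))
        cand$entities <- sort(unique(c(cand$entities, ent)))
        cand$sources[[length(cand$sources) + 1L]] <- data.frame(
          pmid = sentences$pmid[i], sent_index = sentences$sent_index[i],
          pattern_id = pid, stringsAsFactors = FALSE)
        bucket[[norm]] <- cand
      }
    }
  }
  rows <- lapply(seq_along(order_seen), function(k) {
    c0 <- bucket[[order_seen[k]]]
    src <- unique(do.call(rbind, c0$sources))
    list(pm_id = paste0("PM", k), surface = c0$surface,
         normalized = c0$normalized, qualities = c0$qualities,
         entities = c0$entities, sources = src)
  })
  candidates_frame(rows)
}

candidates_frame <- function(rows) {
  df <- data.frame(
    pm_id = vapply(rows, `[[`, character(1), "pm_id"),
    surface = vapply(rows, `[[`, character(1), "surface"),
    normalized = vapply(rows, `[[`, character(1), "normalized"),
    df = rep(NA_integer_, length(rows)),
    stringsAsFactors = FALSE)
  df$qualities <- lapply(rows, `[[`, "qualities")
  df$entities <- lapply(rows, `[[`, "entities")
  df$sources <- lapply(rows, `[[`, "sources")
  df$df_pmids <- rep(list(character(0)), length(rows))
  class(df) <- c("pm_candidates", "data.frame")
  df
}

#' @export
print.pm_candidates <- function(x, ...) {
  cat(sprintf("<pm_candidates: %d terms>\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(x[, c("pm_id", "surface", "normalized", "df")], 10L)
    print.data.frame(show)
    if (nrow(x) > 10L) cat("...\n")
  }
  invisible(x)
}

#' Populate document frequencies and filter candidates
#'
#' Looks each candidate's normalized term up in a [document_index()],
#' records the supporting PMIDs and their count (`df`), and keeps exactly the
#' candidates with `df >= min_df` (inclusive, so `min_df = 10` keeps a
#' df-10 term).  Terms absent from the index get `df = 0`.  Order preserved.
#'
#' @param candidates A `pm_candidates` frame.
#' @param index A [document_index()].
#' @param min_df Minimum document frequency (default 10).
#' @return Filtered `pm_candidates` with `df` and `df_pmids` populated.
#' @export
filter_by_df <- function(candidates, index, min_df = 10L) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    pmids <- index_lookup(index, candidates$normalized[i])
    candidates$df_pmids[[i]] <- pmids
    candidates$df[i] <- length(pmids)
  }
  candidates[candidates$df >= min_df, , drop = FALSE]
}

#' Stratify candidates by document frequency
#'
#' Counts and percentages (to one decimal place) of candidates with document
#' frequency at or above each threshold, over the full candidate list.
#'
#' @param candidates A `pm_candidates` frame with `df` populated, or an
#'   integer vector of document frequencies.
#' @param thresholds Integer df thresholds; the default reports the share
#'   with at least one hit and the >=10 / >=25 / >=10,000 strata.
#' @return Data frame with columns `threshold`, `count`, `pct`.
#' @export
stratify_df <- function(candidates, thresholds = c(1L, 10L, 25L, 10000L)) {
  dfs <- if (is.numeric(candidates)) as.integer(candidates) else candidates$df
  n <- length(dfs)
  counts <- vapply(thresholds, function(t) sum(dfs >= t, na.rm = TRUE), integer(1))
  pct <- if (n == 0L) rep(0, length(thresholds)) else round(100 * counts / n, 1)
  data.frame(threshold = thresholds, count = counts, pct = pct)
}
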