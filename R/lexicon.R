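#' Ontology lexicons
#'
#' A lexicon maps lowercased surface terms (one or more tokens) to concept
#' identifiers within one ontology namespace (PATO, FMA, HP, DOID, ...).
#' Lexicons are the local stand-in for web-service concept annotators: any
#' dictionary -- or the output of a statistical tagger, converted to term
#' lists -- can be plugged in as data.
#'
#' @param namespace Uppercase ontology tag.  Must not contain `/` or `|`
#'   (they are regex and serialization delimiters in the pattern dialect).
#' @param terms Character vector of surface terms.
#' @param ids Concept identifier for each term (recycled per term; a term may
#'   appear on several rows with different identifiers).
#' @return An object of class `pm_lexicon` with fields `namespace` and
#'   `entries` (named list: lowercased term -> character vector of
#'   `NAMESPACE:ID` free identifiers).
#' @export
lexicon <- function(namespace, terms = character(0), ids = character(0)) {
  stopifnot(length(namespace) == 1L, nzchar(namespace))
  if (grepl("[/|]", namespace) || namespace != toupper(namespace)) {
    stop("namespace must be uppercase and contain no '/' or '|': ", namespace)
  }
  stopifnot(length(terms) == length(ids), all(nzchar(terms)))
  entries <- list()
  lt <- tolower(trimws(terms))
  for (i in seq_along(lt)) {
    entries[[lt[i]]] <- unique(c(entries[[lt[i]]], ids[i]))
  }
  structure(list(namespace = namespace, entries = entries),
            class = "pm_lexicon")
}

#' @export
print.pm_lexicon <- function(x, ...) {
  cat(sprintf("<pm_lexicon %s: %d terms>\n", x$namespace, length(x$entries)))
  invisible(x)
}

#' Load a lexicon from TSV or OBO
#'
#' TSV format: header `term, concept_id, namespace`; every row must carry the
#' same namespace.  OBO 1.2 format: `[Term]` stanzas; the term name and all
#' `EXACT` synonyms become entries for the stanza's `id`; the namespace is
#' supplied by the caller (OBO id prefixes are not trusted to equal it).
#' Duplicate (term, id) rows are deduplicated silently.
#'
#' @param path File path.
#' @param format `"tsv"` or `"obo"`.
#' @param namespace Required for OBO input; ignored for TSV.
#' @return A [lexicon()].
#' @export
load_lexicon <- function(path, format = c("tsv", "obo"), namespace = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) == 0L) stop("empty lexicon file: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("term", "concept_id", "namespace")
    if (!identical(header[seq_along(need)], need)) {
      stop("lexicon TSV must have header: term\tconcept_id\tnamespace")
    }
    body <- lines[-1]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 3L)
    if (length(bad)) {
      stop(sprintf("malformed lexicon row at line %d: %s",
                   bad[1] + 1L, body[bad[1]]))
    }
    term <- vapply(parts, `[[`, character(1), 1L)
    id <- vapply(parts, `[[`, character(1), 2L)
    ns <- unique(vapply(parts, `[[`, character(1), 3L))
    if (length(ns) > 1L) stop("mixed namespaces in one lexicon file: ",
                              paste(ns, collapse = ", "))
    lexicon(ns, term, id)
  } else {
    if (is.null(namespace)) stop("OBO loading requires an explicit namespace")
    lines <- readLines(path, encoding = "UTF-8")
    terms <- character(0)
    ids <- character(0)
    cur_id <- NA_character_
    in_term <- FALSE
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "[Term]") {
        in_term <- TRUE
        cur_id <- NA_character_
      } else if (grepl("^\\[", ln)) {
        in_term <- FALSE
      } else if (in_term && startsWith(ln, "id:")) {
        cur_id <- trimws(sub("^id:", "", ln))
      } else if (in_term && startsWith(ln, "name:")) {
        terms <- c(terms, trimws(sub("^name:", "", ln)))
        ids <- c(ids, cur_id)
      } else if (in_term && startsWith(ln, "synonym:")) {
        m <- regmatches(ln, regexec('^synonym: "([^"]*)" EXACT', ln))[[1]]
        if (length(m) == 2L) {
          terms <- c(terms, m[2])
          ids <- c(ids, cur_id)
        }
      }
    }
    if (anyNA(ids)) stop("OBO stanza with name/synonym before id")
    lexicon(namespace, terms, ids)
  }
}

#' Annotate tokens with ontology concepts
#'
#' Dictionary matching per namespace: greedy leftmost-longest matching,
#' case-insensitive, scanning left to right.  Namespaces are matched
#' independently, so spans from different ontologies may overlap; within one
#' namespace each token belongs to at most one matched span (a span carrying
#' several concept identifiers yields one row per identifier).
#'
#' @param tokens Non-empty character vector of tokens.
#' @param lexicons List of [lexicon()] objects.
#' @return Data frame with columns `token_start`, `token_end` (0-based,
#'   half-open), `namespace`, `concept_id`, ordered by namespace then span.
#' @export
annotate <- function(tokens, lexicons) {
  stopifnot(length(tokens) > 0L)
  if (inherits(lexicons, "pm_lexicon")) lexicons <- list(lexicons)
  low <- tolower(tokens)
  n <- length(low)
  out <- list()
  for (lex in lexicons) {
    max_len <- max(c(1L, lengths(strsplit(names(lex$entries), " ", fixed = TRUE))))
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      hit_ids <- NULL
      for (len in seq(min(max_len, n - i + 1L), 1L)) {
        key <- paste(low[i:(i + len - 1L)], collapse = " ")
        ids <- lex$entries[[key]]
        if (!is.null(ids)) {
          hit_len <- len
          hit_ids <- ids
          break
        }
      }
      if (hit_len > 0L) {
        for (id in hit_ids) {
          out[[length(out) + 1L]] <- data.frame(
            token_start = i - 1L, token_end = i - 1L + hit_len,
            namespace = lex$namespace, concept_id = id,
            stringsAsFactors = FALSE)
        }
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(token_start = integer(0), token_end = integer(0),
                      namespace = character(0), concept_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
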