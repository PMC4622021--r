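#' Export the linked phenotype database
#'
#' Writes one record per candidate with the database field set: the term and
#' its accession, the annotation date, links to external vocabularies
#' (quality and entity concepts), the associated OMIM disorders found by rule
#' mining (with support count and p-value), and links to occurrences in the
#' literature (source sentences and supporting PMIDs).  XML output validates
#' against the schema shipped at `inst/schema/phenodb.xsd`; `jsonl` writes an
#' equivalent JSON-lines mirror.  Field order is deterministic.
#'
#' @param candidates A `pm_candidates` frame.
#' @param rules A `pm_rules` frame whose antecedents are `p/` +
#'   candidate normalized terms (may have zero rows).
#' @param path Output file.
#' @param format `"xml"` or `"jsonl"`.
#' @param date Annotation date string (default today); pass a fixed value
#'   for reproducible output.
#' @return `path`, invisibly.
#' @export
export_records <- function(candidates, rules, path, format = c("xml", "jsonl"),
                           date = format(Sys.Date())) {
  format <- match.arg(format)
  known <- paste0("p/", candidates$normalized)
  if (nrow(rules) > 0) {
    dangling <- setdiff(rules$antecedent, known)
    if (length(dangling)) {
      stop("rule(s) reference unknown candidates: ",
           paste(dangling, collapse = ", "))
    }
  }
  recs <- lapply(seq_len(nrow(candidates)), function(i) {
    ri <- if (nrow(rules)) {
      rules[rules$antecedent == known[i], , drop = FALSE]
    } else rules
    list(cand = candidates[i, , drop = FALSE], rules = ri)
  })
  if (format == "xml") {
    export_xml(recs, path, date)
  } else {
    export_jsonl(recs, path, date)
  }
  invisible(path)
}

export_xml <- function(recs, path, date) {
  doc <- xml2::xml_new_root("phenotypeDatabase")
  for (r in recs) {
    cand <- r$cand
    ph <- xml2::xml_add_child(doc, "phenotype", id = cand$pm_id)
    xml2::xml_add_child(ph, "term", cand$normalized)
    xml2::xml_add_child(ph, "surface", cand$surface)
    xml2::xml_add_child(ph, "annotated", date)
    con <- xml2::xml_add_child(ph, "concepts")
    for (q in cand$qualities[[1]]) {
      xml2::xml_add_child(con, "concept", role = "quality", id = q)
    }
    for (e in cand$entities[[1]]) {
      xml2::xml_add_child(con, "concept", role = "entity", id = e)
    }
    dis <- xml2::xml_add_child(ph, "disorders")
    if (nrow(r$rules)) {
      for (j in seq_len(nrow(r$rules))) {
        xml2::xml_add_child(
          dis, "disorder",
          name = sub("^d/", "", r$rules$consequent[j]),
          supportCount = format(r$rules$support_count[j], scientific = FALSE),
          confidence = sprintf("%.6g", r$rules$confidence[j]),
          pValue = sprintf("%.6g", r$rules$p_value[j]))
      }
    }
    occ <- xml2::xml_add_child(
      ph, "occurrences",
      df = format(if (is.na(cand$df)) 0L else cand$df, scientific = FALSE))
    src <- cand$sources[[1]]
    if (!is.null(src) && nrow(src)) {
      for (j in seq_len(nrow(src))) {
        xml2::xml_add_child(occ, "doc", pmid = src$pmid[j],
                            sentence = as.character(src$sent_index[j]),
                            pattern = src$pattern_id[j])
      }
    }
    for (p in cand$df_pmids[[1]]) xml2::xml_add_child(occ, "pmid", p)
  }
  xml2::write_xml(doc, path)
}

export_jsonl <- function(recs, path, date) {
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in recs) {
    cand <- r$cand
    obj <- list(
      pm_id = cand$pm_id, term = cand$normalized, surface = cand$surface,
      annotated = date,
      qualities = cand$qualities[[1]], entities = cand$entities[[1]],
      disorders = if (nrow(r$rules)) data.frame(
        name = sub("^d/", "", r$rules$consequent),
        support_count = r$rules$support_count,
        confidence = r$rules$confidence,
        p_value = r$rules$p_value, stringsAsFactors = FALSE) else list(),
      df = if (is.na(cand$df)) 0L else cand$df,
      sources = cand$sources[[1]],
      df_pmids = cand$df_pmids[[1]])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
}

#' Validate an exported XML database against the shipped schema
#'
#' @param path XML file written by [export_records()].
#' @return `TRUE` if valid, otherwise `FALSE` with validation errors
#'   attached.
#' @export
validate_records <- function(path) {
  schema <- xml2::read_xml(system.file("schema", "phenodb.xsd",
                                       package = "phenomine"))
  xml2::xml_validate(xml2::read_xml(path), schema)
}

#' Re-import an exported XML database
#'
#' Inverse of [export_records()] for the candidate fields (rules are
#' re-attached from their own TSV).
#'
#' @param path XML file written by [export_records()].
#' @return A `pm_candidates` frame.
#' @export
import_records <- function(path) {
  doc <- xml2::read_xml(path)
  phs <- xml2::xml_find_all(doc, "phenotype")
  rows <- lapply(phs, function(ph) {
    src_nodes <- xml2::xml_find_all(ph, "occurrences/doc")
    src <- data.frame(
      pmid = xml2::xml_attr(src_nodes, "pmid"),
      sent_index = as.integer(xml2::xml_attr(src_nodes, "sentence")),
      pattern_id = xml2::xml_attr(src_nodes, "pattern"),
      stringsAsFactors = FALSE)
    list(pm_id = xml2::xml_attr(ph, "id"),
         surface = xml2::xml_text(xml2::xml_find_first(ph, "surface")),
         normalized = xml2::xml_text(xml2::xml_find_first(ph, "term")),
         qualities = xml2::xml_attr(
           xml2::xml_find_all(ph, "concepts/concept[@role='quality']"), "id"),
         entities = xml2::xml_attr(
           xml2::xml_find_all(ph, "concepts/concept[@role='entity']"), "id"),
         sources = src,
         df = as.integer(xml2::xml_attr(
           xml2::xml_find_first(ph, "occurrences"), "df")),
         df_pmids = xml2::xml_text(xml2::xml_find_all(ph, "occurrences/pmid")))
  })
  out <- candidates_frame(rows)
  out$df <- vapply(rows, `[[`, integer(1), "df")
  out$df_pmids <- lapply(rows, `[[`, "df_pmids")
  out
}
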