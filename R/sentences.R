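#' Sentence records
#'
#' Sentences are carried as a plain data frame with one row per sentence and
#' columns `pmid` (document identifier), `sent_index` (non-negative integer
#' position within the document), `text` (raw sentence) and `ptb_tree`
#' (single-line bracket string, possibly `NA` before parsing).  This mirrors
#' the on-disk TSV interchange format.
#'
#' @param pmid Character vector of document identifiers (non-empty).
#' @param sent_index Integer vector of sentence positions.
#' @param text Character vector of raw sentences.
#' @param ptb_tree Character vector of bracket strings (or `NA`).
#' @return A `data.frame` with the four columns above.
#' @export
sentence_records <- function(pmid, sent_index, text, ptb_tree = NA_character_) {
  stopifnot(all(nzchar(pmid)), all(sent_index >= 0))
  data.frame(pmid = as.character(pmid),
             sent_index = as.integer(sent_index),
             text = as.character(text),
             ptb_tree = as.character(ptb_tree),
             stringsAsFactors = FALSE)
}

#' Read / write the sentence TSV format
#'
#' Tab-separated UTF-8 with header `pmid, sent_index, text, ptb_tree`.
#'
#' @param path File path.
#' @return `read_sentences` returns a sentence data frame;
#'   `write_sentences` returns `path` invisibly.
#' @export
read_sentences <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("pmid", "sent_index", "text", "ptb_tree")
  if (!all(need %in% names(df))) {
    stop("sentence file must have columns: ", paste(need, collapse = ", "))
  }
  sentence_records(df$pmid, as.integer(df$sent_index), df$text, df$ptb_tree)
}

#' @rdname read_sentences
#' @param sentences Sentence data frame.
#' @export
write_sentences <- function(sentences, path) {
  utils::write.table(sentences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default abnormality trigger stems
#'
#' The eleven lowercase prefix stems used to sample sentences likely to
#' describe abnormal phenotypes.  The set is a core group of synonyms of the
#' PATO quality "abnormal" (PATO:0000460) expanded with common morphological
#' variants; each stem matches any token that begins with it
#' (case-insensitively), i.e. `inactiv` matches "inactivation".
#'
#' @return Character vector of 11 stems.
#' @export
trigger_stems <- function() {
  c("abnormal", "characteristic", "aberra", "defect", "atypical",
    "unusual", "irregular", "anomal", "unhealthy", "inactiv", "inadeq")
}

#' Whitespace/punctuation tokenizer
#'
#' Fallback tokenization used when pre-tokenized input is unavailable:
#' splits on whitespace, then strips leading/trailing punctuation from each
#' token.  Callers with parser-compatible tokenizations should supply their
#' own tokens instead.
#'
#' @param text Character vector of sentences.
#' @return List of character token vectors.
#' @export
tokenize <- function(text) {
  lapply(strsplit(text, "[[:space:]]+"), function(toks) {
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    toks[nzchar(toks)]
  })
}

token_has_trigger <- function(tokens, stems) {
  toks <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", tokens))
  any(vapply(stems, function(s) any(startsWith(toks, s)), logical(1)))
}

#' Select sentences containing an abnormality trigger
#'
#' Keeps exactly the sentences in which at least one token begins with one of
#' the trigger stems, case-insensitively, after stripping surrounding
#' punctuation.  Tokens come from the tree yield when a parse is present,
#' otherwise from [tokenize()] on the raw text.  Order is preserved; the
#' operation is idempotent.
#'
#' @param sentences Sentence data frame (see [sentence_records()]).
#' @param stems Character vector of prefix stems; default [trigger_stems()].
#' @return The selected subset of `sentences`.
#' @export
select_trigger_sentences <- function(sentences, stems = trigger_stems()) {
  stopifnot(is.character(stems), !any(grepl("[[:space:]]", stems)))
  if (nrow(sentences) == 0L) return(sentences)
  stems <- tolower(stems)
  keep <- vapply(seq_len(nrow(sentences)), function(i) {
    tr <- sentences$ptb_tree[i]
    toks <- if (!is.na(tr) && nzchar(tr)) {
      tree_yield(read_ptb(tr))
    } else {
      tokenize(sentences$text[i])[[1]]
    }
    token_has_trigger(toks, stems)
  }, logical(1))
  sentences[keep, , drop = FALSE]
}
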