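#' Attach semantic annotations to a parse tree
#'
#' Builds the semantically typed tree consumed by the pattern matcher: for
#' every annotated token, the preterminal dominating that leaf gains an extra
#' final child labeled `SEM` whose single leaf is the serialized concept set
#' (`;`-joined, sorted `NAMESPACE:ID` entries).  Multi-token annotations
#' project onto every covered token's preterminal, because the extraction
#' patterns test individual preterminals (`JJ`, `/NN.?/`).  Stripping the
#' `SEM` nodes ([strip_sem()]) recovers the original tree exactly.
#'
#' @param tree A [ptree] whose yield has as many word leaves as the token
#'   sequence the annotations refer to.
#' @param annotations Data frame from [annotate()] (0-based half-open token
#'   spans with `namespace` and `concept_id`).
#' @return The annotated [ptree].
#' @export
assemble_semantic_tree <- function(tree, annotations) {
  yield_len <- length(tree_yield(tree))
  concepts <- vector("list", yield_len)
  if (nrow(annotations) > 0L) {
    if (any(annotations$token_start < 0L) ||
        any(annotations$token_end > yield_len) ||
        any(annotations$token_start >= annotations$token_end)) {
      stop("annotation span out of range for a yield of length ", yield_len)
    }
    for (i in seq_len(nrow(annotations))) {
      idx <- seq(annotations$token_start[i] + 1L, annotations$token_end[i])
      tag <- paste0(annotations$namespace[i], ":", annotations$concept_id[i])
      # concept_id may already carry the namespace prefix; don't double it
      if (startsWith(annotations$concept_id[i],
                     paste0(annotations$namespace[i], ":"))) {
        tag <- annotations$concept_id[i]
      }
      for (j in idx) concepts[[j]] <- c(concepts[[j]], tag)
    }
  }
  leaf_no <- 0L
  decorate <- function(node) {
    if (is_leaf(node)) return(node)
    is_preterminal <- all(vapply(node$children, is_leaf, logical(1))) &&
      node$label != "SEM"
    if (is_preterminal) {
      leaf_no <<- leaf_no + length(node$children)
      cset <- concepts[[leaf_no]]
      if (!is.null(cset)) {
        sem_leaf <- ptree(paste(sort(unique(cset)), collapse = ";"))
        node$children <- c(node$children, list(ptree("SEM", list(sem_leaf))))
      }
      return(node)
    }
    node$children <- lapply(node$children, decorate)
    node
  }
  decorate(tree)
}

#' Remove SEM annotation nodes
#'
#' @param tree An annotated [ptree].
#' @return The tree with every `SEM` subtree removed.
#' @export
strip_sem <- function(tree) {
  if (is_leaf(tree)) return(tree)
  kept <- Filter(function(ch) ch$label != "SEM", tree$children)
  tree$children <- lapply(kept, strip_sem)
  tree
}

#' Annotate a batch of sentence records
#'
#' Convenience wrapper running [annotate()] + [assemble_semantic_tree()] on
#' each parsed sentence; the annotated tree replaces `ptb_tree`.
#'
#' @param sentences Sentence data frame with parsed `ptb_tree`.
#' @param lexicons List of [lexicon()] objects.
#' @return Sentence data frame whose `ptb_tree` column carries SEM nodes.
#' @export
annotate_sentences <- function(sentences, lexicons) {
  sentences$ptb_tree <- vapply(sentences$ptb_tree, function(s) {
    tree <- read_ptb(s)
    toks <- tree_yield(tree)
    write_ptb(assemble_semantic_tree(tree, annotate(toks, lexicons)))
  }, character(1), USE.NAMES = FALSE)
  sentences
}
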