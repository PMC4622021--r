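#' Phrase-structure parse trees
#'
#' A `ptree` is the package's constituency-tree container: a recursive list
#' with a `label` (phrase category at internal nodes, part-of-speech at
#' preterminals, the word itself at leaves) and an ordered list of `children`
#' (empty at leaves).  Trees are read from and written to single-line
#' Penn-Treebank bracket notation, the interchange format produced by
#' constituency parsers such as BLLIP/Charniak-Johnson.
#'
#' @param label Non-empty node label string.
#' @param children List of `ptree` children (possibly empty).
#' @return An object of class `ptree`.
#' @examples
#' t <- ptree("NP", list(ptree_leaf("DT", "a"), ptree_leaf("NN", "defect")))
#' write_ptb(t)
#' @export
ptree <- function(label, children = list()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, children = children), class = "ptree")
}

#' @rdname ptree
#' @param word Leaf word dominated by the preterminal `label`.
#' @export
ptree_leaf <- function(label, word) {
  ptree(label, list(ptree(word)))
}

#' @export
print.ptree <- function(x, ...) {
  cat(write_ptb(x), "\n")
  invisible(x)
}

is_leaf <- function(node) length(node$children) == 0L

#' Read a Penn-Treebank bracketed tree
#'
#' Parses one tree in bracket notation, e.g. `"(NP (DT a) (NN defect))"`.
#' Labels and words are preserved verbatim (no tag stripping), so trees
#' round-trip exactly through [write_ptb()].
#'
#' @param text A single balanced bracket string containing one tree.
#' @return A [ptree].
#' @export
read_ptb <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty input: no tree to read")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  skip_ws <- function() {
    while (pos <= n && chars[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
  }
  read_token <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")", " ", "\t", "\n", "\r")) {
      pos <<- pos + 1L
    }
    if (pos == start) stop(sprintf("parse error at offset %d: expected label", start))
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node <- function() {
    skip_ws()
    if (pos > n) stop(sprintf("parse error at offset %d: unexpected end of input", pos))
    if (chars[pos] != "(") {
      # bare token: a leaf
      return(ptree(read_token()))
    }
    open_at <- pos
    pos <<- pos + 1L
    skip_ws()
    if (pos > n) {
      stop(sprintf("parse error at offset %d: unclosed '(' opened at %d", pos, open_at))
    }
    label <- read_token()
    kids <- list()
    repeat {
      skip_ws()
      if (pos > n) {
        stop(sprintf("parse error at offset %d: unclosed '(' opened at %d", pos, open_at))
      }
      if (chars[pos] == ")") {
        pos <<- pos + 1L
        break
      }
      kids[[length(kids) + 1L]] <- parse_node()
    }
    ptree(label, kids)
  }

  skip_ws()
  tree <- parse_node()
  skip_ws()
  if (pos <= n) {
    stop(sprintf("parse error at offset %d: trailing content after tree", pos))
  }
  tree
}

#' Write a tree in Penn-Treebank bracket notation
#'
#' Inverse of [read_ptb()]: produces a single-line bracket string.
#'
#' @param tree A [ptree].
#' @return A character scalar.
#' @export
write_ptb <- function(tree) {
  stopifnot(inherits(tree, "ptree"))
  if (is_leaf(tree)) return(tree$label)
  kids <- vapply(tree$children, write_ptb, character(1))
  paste0("(", tree$label, " ", paste(kids, collapse = " "), ")")
}

#' Leaf yield of a tree
#'
#' Left-to-right sequence of leaf labels.  With `skip_sem = TRUE` (the
#' default) subtrees rooted at `SEM` nodes -- the semantic annotations
#' attached by [assemble_semantic_tree()] -- are excluded, so the yield of an
#' annotated tree is its word token sequence.
#'
#' @param tree A [ptree].
#' @param skip_sem Exclude `SEM` subtrees from the yield.
#' @return Character vector of leaf labels.
#' @export
tree_yield <- function(tree, skip_sem = TRUE) {
  if (is_leaf(tree)) return(tree$label)
  out <- character(0)
  for (ch in tree$children) {
    if (skip_sem && ch$label == "SEM") next
    out <- c(out, tree_yield(ch, skip_sem))
  }
  out
}

#' Structural tree equality
#'
#' @param a,b Trees to compare.
#' @return `TRUE` iff labels and child structure agree everywhere.
#' @export
tree_equal <- function(a, b) {
  if (a$label != b$label) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (i in seq_along(a$children)) {
    if (!tree_equal(a$children[[i]], b$children[[i]])) return(FALSE)
  }
  TRUE
}

#' Count nodes in a tree
#' @param tree A [ptree].
#' @return Integer node count (leaves included).
#' @export
tree_size <- function(tree) {
  1L + sum(vapply(tree$children, tree_size, integer(1)))
}

# Flatten a tree into parallel vectors indexed by preorder position:
#   label[i], parent[i] (0 for root), kids[[i]] (preorder ids of children),
#   pos[i] (1-based index among siblings).  Used by the pattern matchers.
flatten_tree <- function(tree) {
  labels <- character(0)
  parent <- integer(0)
  pos <- integer(0)
  kids <- list()
  walk <- function(node, par, sib_pos) {
    id <- length(labels) + 1L
    labels[id] <<- node$label
    parent[id] <<- par
    pos[id] <<- sib_pos
    kids[[id]] <<- integer(0)
    for (i in seq_along(node$children)) {
      cid <- walk(node$children[[i]], id, i)
      kids[[id]] <<- c(kids[[id]], cid)
    }
    id
  }
  walk(tree, 0L, 1L)
  list(labels = labels, parent = parent, pos = pos, kids = kids,
       n = length(labels))
}

# Subtree rooted at preorder id `root` of the flattened original.
subtree_at <- function(tree, root) {
  found <- NULL
  i <- 0L
  walk <- function(node) {
    i <<- i + 1L
    if (i == root) {
      found <<- node
      return(TRUE)
    }
    for (ch in node$children) if (walk(ch)) return(TRUE)
    FALSE
  }
  walk(tree)
  found
}
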