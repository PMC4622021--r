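#' Tree-pattern dialect
#'
#' The extraction patterns use a small fragment of the Stanford Tregex
#' language over annotated constituency trees:
#'
#' * node tests: a plain identifier (`NP`, `JJ`, `SEM`) matches a label by
#'   exact string equality; a `/regex/` form matches by unanchored regex
#'   search, so `/NN.?/` matches `NN`, `NNS`, `NNP`, `NNPS` (but not `NP`)
#'   and `/PATO/` hits a serialized concept set such as
#'   `PATO:0000574;SNOMEDCT:52765003`;
#' * `A < B`: B matches an immediate child of the node matched by A;
#' * `A ++ B`: B matches a later sister of A (same parent, strictly later
#'   position, not necessarily adjacent);
#' * `A + CC B`: coordination -- A and B are sisters with a `CC`-labeled
#'   sister strictly between them.
#'
#' Relation clauses chain on their head node, so in
#' `NP < (JJ < (SEM < /PATO/) ++ (/NN.?/ ...))` both the `<` and the `++`
#' constrain the `JJ` node.  Parentheses group.
#'
#' @name tregex
NULL

new_pnode <- function(test_type, test_value) {
  list(test_type = test_type,  # "exact" or "regex"
       test_value = test_value,
       rels = list())           # list of list(op =, pat =)
}

tgx_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    c0 <- chars[i]
    if (c0 %in% c(" ", "\t")) {
      i <- i + 1L
    } else if (c0 == "(") {
      toks[[length(toks) + 1L]] <- list(type = "(", at = i); i <- i + 1L
    } else if (c0 == ")") {
      toks[[length(toks) + 1L]] <- list(type = ")", at = i); i <- i + 1L
    } else if (c0 == "<") {
      toks[[length(toks) + 1L]] <- list(type = "<", at = i); i <- i + 1L
    } else if (c0 == "+") {
      if (i < n && chars[i + 1L] == "+") {
        toks[[length(toks) + 1L]] <- list(type = "++", at = i); i <- i + 2L
      } else {
        toks[[length(toks) + 1L]] <- list(type = "+", at = i); i <- i + 1L
      }
    } else if (c0 == "/") {
      j <- i + 1L
      while (j <= n && chars[j] != "/") j <- j + 1L
      if (j > n) stop(sprintf("pattern syntax error at position %d: unterminated /regex/", i))
      toks[[length(toks) + 1L]] <- list(
        type = "regex", value = paste(chars[(i + 1L):(j - 1L)], collapse = ""),
        at = i)
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !chars[j] %in% c(" ", "\t", "(", ")", "<", "+", "/")) {
        j <- j + 1L
      }
      toks[[length(toks) + 1L]] <- list(
        type = "ident", value = paste(chars[i:(j - 1L)], collapse = ""), at = i)
      i <- j
    }
  }
  toks
}

#' Parse a tree-pattern expression
#'
#' @param text Pattern string in the dialect documented at [tregex].
#' @return An object of class `pm_pattern`: a recursive AST of node tests
#'   with ordered relation clauses (`child`, `sister`, `coord`).
#' @export
parse_pattern <- function(text) {
  toks <- tgx_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }

  parse_unit <- function() {
    t <- peek()
    if (is.null(t)) stop("pattern syntax error: unexpected end of pattern")
    if (t$type == "(") {
      advance()
      p <- parse_seq()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") {
        stop(sprintf("pattern syntax error at position %d: expected ')'",
                     if (is.null(t2)) t$at else t2$at))
      }
      advance()
      p
    } else if (t$type == "ident") {
      advance()
      new_pnode("exact", t$value)
    } else if (t$type == "regex") {
      advance()
      new_pnode("regex", t$value)
    } else {
      stop(sprintf("pattern syntax error at position %d: unexpected '%s'",
                   t$at, t$type))
    }
  }

  parse_seq <- function() {
    head <- parse_unit()
    repeat {
      t <- peek()
      if (is.null(t) || !t$type %in% c("<", "++", "+")) break
      advance()
      op <- switch(t$type, "<" = "child", "++" = "sister", "+" = "coord")
      if (op == "coord") {
        cc <- peek()
        if (is.null(cc) || cc$type != "ident" || cc$value != "CC") {
          stop(sprintf("pattern syntax error at position %d: '+' must be followed by CC",
                       t$at))
        }
        advance()
      }
      operand <- parse_unit()
      head$rels[[length(head$rels) + 1L]] <- list(op = op, pat = operand)
    }
    head
  }

  p <- parse_seq()
  t <- peek()
  if (!is.null(t)) {
    stop(sprintf("pattern syntax error at position %d: unexpected '%s'",
                 t$at, t$type))
  }
  class(p) <- "pm_pattern"
  p
}

#' Serialize a pattern AST back to pattern syntax
#'
#' Re-parsing the output yields a structurally identical AST.
#'
#' @param pattern A `pm_pattern`.
#' @return A pattern string.
#' @export
format_pattern <- function(pattern) {
  fmt <- function(p, top) {
    test <- if (p$test_type == "regex") paste0("/", p$test_value, "/") else p$test_value
    if (length(p$rels) == 0L) return(test)
    parts <- test
    for (r in p$rels) {
      op <- switch(r$op, child = "<", sister = "++", coord = "+ CC")
      parts <- paste(parts, op, fmt(r$pat, FALSE))
    }
    if (top) parts else paste0("(", parts, ")")
  }
  fmt(pattern, TRUE)
}

#' @export
print.pm_pattern <- function(x, ...) {
  cat(format_pattern(x), "\n")
  invisible(x)
}

# number pattern nodes in preorder; returns list(pattern-with-ids, count)
index_pattern <- function(pattern) {
  k <- 0L
  walk <- function(p) {
    k <<- k + 1L
    p$id <- k
    p$rels <- lapply(p$rels, function(r) {
      r$pat <- walk(r$pat)
      r
    })
    p
  }
  p <- walk(pattern)
  list(pattern = p, n = k)
}

node_test_ok <- function(p, label) {
  if (p$test_type == "exact") identical(label, p$test_value)
  else grepl(p$test_value, label)
}

# candidate tree nodes for a relation of `op` anchored at tree node `n`
rel_candidates <- function(op, n, tab) {
  if (op == "child") return(tab$kids[[n]])
  par <- tab$parent[n]
  if (par == 0L) return(integer(0))
  sibs <- tab$kids[[par]]
  later <- sibs[tab$pos[sibs] > tab$pos[n]]
  if (op == "sister") return(later)
  # coord: a CC-labeled sister strictly between n and the candidate
  keep <- vapply(later, function(y) {
    between <- sibs[tab$pos[sibs] > tab$pos[n] & tab$pos[sibs] < tab$pos[y]]
    any(tab$labels[between] == "CC")
  }, logical(1))
  later[keep]
}

# all bindings of (indexed) pattern p rooted at tree node n; each binding is
# an integer vector of length npat (NA where unbound)
bindings_at <- function(p, n, tab, npat) {
  if (!node_test_ok(p, tab$labels[n])) return(list())
  base <- rep(NA_integer_, npat)
  base[p$id] <- n
  acc <- list(base)
  for (r in p$rels) {
    cands <- rel_candidates(r$op, n, tab)
    sub <- list()
    for (cn in cands) {
      sub <- c(sub, bindings_at(r$pat, cn, tab, npat))
    }
    if (length(sub) == 0L) return(list())
    new_acc <- vector("list", length(acc) * length(sub))
    k <- 0L
    for (a in acc) for (s in sub) {
      k <- k + 1L
      merged <- a
      merged[!is.na(s)] <- s[!is.na(s)]
      new_acc[[k]] <- merged
    }
    acc <- new_acc
  }
  acc
}

order_bindings <- function(bindings) {
  if (length(bindings) <= 1L) return(bindings)
  keys <- vapply(bindings, function(b) {
    paste(sprintf("%06d", ifelse(is.na(b), 0L, b)), collapse = ",")
  }, character(1))
  bindings[order(keys)]
}

#' Match a pattern against a tree
#'
#' Returns one result per distinct binding of pattern nodes to tree nodes.
#' Results are ordered by preorder position of the matched root, then by
#' lexicographic binding order.  The input tree is not modified.
#'
#' @param pattern A `pm_pattern` from [parse_pattern()].
#' @param tree A [ptree] (usually SEM-annotated).
#' @return List of match results, each a list with `root` (preorder index of
#'   the matched root in `tree`) and `bindings` (integer vector mapping
#'   pattern-node preorder ids to tree-node preorder ids).
#' @export
match_pattern <- function(pattern, tree) {
  stopifnot(inherits(pattern, "pm_pattern"), inherits(tree, "ptree"))
  idx <- index_pattern(pattern)
  tab <- flatten_tree(tree)
  out <- list()
  for (n in seq_len(tab$n)) {
    bs <- order_bindings(bindings_at(idx$pattern, n, tab, idx$n))
    for (b in bs) {
      out[[length(out) + 1L]] <- list(root = n, bindings = b)
    }
  }
  out
}

#' Brute-force matching oracle
#'
#' Independent verification oracle: enumerates every assignment of pattern
#' nodes to label-compatible tree nodes and filters by the relation
#' predicates, with no search-order logic shared with [match_pattern()].
#' Refuses trees larger than `max_nodes` (default 40) or assignments spaces
#' larger than `max_space`.
#'
#' @inheritParams match_pattern
#' @param max_nodes Tractability guard on tree size.
#' @param max_space Guard on the assignment-space size.
#' @return Same structure as [match_pattern()], identically ordered.
#' @export
brute_force_match <- function(pattern, tree, max_nodes = 40L,
                              max_space = 5e6) {
  stopifnot(inherits(pattern, "pm_pattern"), inherits(tree, "ptree"))
  if (tree_size(tree) > max_nodes) {
    stop("brute_force_match: tree larger than ", max_nodes, " nodes")
  }
  tab <- flatten_tree(tree)

  # collect pattern nodes (preorder) and the relation constraints among them
  pnodes <- list()
  constraints <- list()   # list(op, head_idx, dep_idx)
  walk <- function(p) {
    id <- length(pnodes) + 1L
    pnodes[[id]] <<- p
    for (r in p$rels) {
      did <- walk(r$pat)
      constraints[[length(constraints) + 1L]] <<- list(
        op = r$op, head = id, dep = did)
    }
    id
  }
  walk(pattern)
  k <- length(pnodes)

  cand <- lapply(pnodes, function(p) {
    which(vapply(tab$labels, function(lb) node_test_ok(p, lb), logical(1)))
  })
  space <- prod(vapply(cand, length, integer(1)))
  if (space == 0) return(list())
  if (space > max_space) {
    stop("brute_force_match: assignment space too large (", space, ")")
  }

  is_child_of <- function(c0, p0) tab$parent[c0] == p0
  is_later_sister <- function(y, x) {
    tab$parent[x] != 0L && tab$parent[y] == tab$parent[x] &&
      tab$pos[y] > tab$pos[x]
  }
  has_cc_between <- function(x, y) {
    sibs <- tab$kids[[tab$parent[x]]]
    mid <- sibs[tab$pos[sibs] > tab$pos[x] & tab$pos[sibs] < tab$pos[y]]
    any(tab$labels[mid] == "CC")
  }

  grid <- expand.grid(rev(cand), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(k)), drop = FALSE]  # column j = pattern node j
  ok <- rep(TRUE, nrow(grid))
  for (con in constraints) {
    h <- grid[[con$head]]
    d <- grid[[con$dep]]
    pass <- switch(con$op,
      child = vapply(seq_along(h), function(i) is_child_of(d[i], h[i]), logical(1)),
      sister = vapply(seq_along(h), function(i) is_later_sister(d[i], h[i]), logical(1)),
      coord = vapply(seq_along(h), function(i) {
        is_later_sister(d[i], h[i]) && has_cc_between(h[i], d[i])
      }, logical(1)))
    ok <- ok & pass
  }
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0L) return(list())
  out <- lapply(seq_len(nrow(grid)), function(i) {
    b <- as.integer(grid[i, ])
    list(root = b[1], bindings = b)
  })
  keys <- vapply(out, function(m) {
    paste(sprintf("%06d", m$bindings), collapse = ",")
  }, character(1))
  out <- out[order(vapply(out, `[[`, integer(1), "root"), keys)]
  # drop duplicate assignments (cannot occur: candidates are distinct nodes)
  out
}

#' The nine built-in phenotype extraction patterns
#'
#' Hand-crafted patterns capturing noun phrases in which a PATO quality
#' modifier is paired with an entity word: three syntactic shapes (plain
#' adjective, ADJP-wrapped adjective, NP coordination) crossed with three
#' entity namespace groups (anatomy/chemical: FMA, RxNORM, ChEBI, MA;
#' phenotype ontologies: MP, HP; disease vocabularies: DOID, ORDO, OMIM).
#'
#' @param parsed If `TRUE` (default) return parsed `pm_pattern` objects
#'   (named `p1`..`p9`); otherwise the raw pattern strings.
#' @return Named list of patterns or character vector.
#' @export
builtin_patterns <- function(parsed = TRUE) {
  path <- system.file("patterns", "phenominer9.tgx", package = "phenomine")
  txt <- read_pattern_file(path)
  if (!parsed) return(txt)
  lapply(txt, parse_pattern)
}

#' Read a pattern file
#'
#' One pattern per line; blank lines and `#` comments ignored.  Patterns are
#' named `p1`, `p2`, ... in file order unless a line has the form
#' `name: pattern`.
#'
#' @param path Pattern file.
#' @return Named character vector of pattern strings.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  nm <- sprintf("p%d", seq_along(lines))
  has_name <- grepl("^[A-Za-z0-9_]+:[[:space:]]", lines)
  nm[has_name] <- sub(":.*$", "", lines[has_name])
  lines[has_name] <- trimws(sub("^[A-Za-z0-9_]+:[[:space:]]", "", lines[has_name]))
  stats::setNames(lines, nm)
}
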