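#' Build PMID transactions from document indexes
#'
#' Each document (PMID) becomes one transaction containing a `p/`-prefixed
#' item for every phenotype whose index list includes the PMID and a
#' `d/`-prefixed item for every disorder.  A disorder's PMID set is the union
#' over its canonical name and all synonyms, unified under the canonical name
#' (so synonym query expansion increases evidence but yields one item).
#' Transactions with fewer than two items are retained: they contribute to
#' the transaction count N over which support fractions are defined.
#'
#' @param phenotype_index [document_index()] keyed by normalized phenotype
#'   terms.
#' @param disorder_vocab A [disorder_vocabulary()].
#' @param disorder_index [document_index()] keyed by canonical names and
#'   synonyms (lowercased lookup).
#' @param on_ambiguous_synonym What to do when one synonym string belongs to
#'   two canonical disorders: `"error"` (default) or `"both"` (credit the
#'   PMIDs to both disorders).
#' @param universe Optional character vector of all PMIDs in the corpus.
#'   PMIDs without any item then become empty transactions, so N counts the
#'   whole corpus; by default N counts only PMIDs retrieved by at least one
#'   query, which is what live per-term retrieval can observe.
#' @return An object of class `pm_transactions`: a named list PMID ->
#'   character item set, with attribute `n_items` (distinct item count).
#' @export
build_transactions <- function(phenotype_index, disorder_vocab, disorder_index,
                               on_ambiguous_synonym = c("error", "both"),
                               universe = NULL) {
  on_ambiguous_synonym <- match.arg(on_ambiguous_synonym)
  owner <- list()  # lowercased synonym -> canonical names seen
  for (i in seq_len(nrow(disorder_vocab))) {
    for (s in tolower(disorder_vocab$synonyms[[i]])) {
      owner[[s]] <- c(owner[[s]], disorder_vocab$canonical_name[i])
    }
  }
  amb <- names(owner)[vapply(owner, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(amb) && on_ambiguous_synonym == "error") {
    stop("synonym(s) shared by multiple canonical disorders: ",
         paste(vapply(amb, function(s) {
           sprintf("'%s' (%s)", s, paste(unique(owner[[s]]), collapse = " / "))
         }, character(1)), collapse = "; "))
  }

  tx <- new.env(parent = emptyenv())
  add_item <- function(pmids, item) {
    for (p in pmids) {
      assign(p, c(get0(p, envir = tx, ifnotfound = character(0)), item),
             envir = tx)
    }
  }
  for (term in index_terms(phenotype_index)) {
    add_item(index_lookup(phenotype_index, term), paste0("p/", term))
  }
  for (i in seq_len(nrow(disorder_vocab))) {
    cname <- disorder_vocab$canonical_name[i]
    queries <- unique(c(cname, disorder_vocab$synonyms[[i]]))
    pmids <- unique(unlist(lapply(queries, function(q)
      index_lookup(disorder_index, q))))
    add_item(pmids, paste0("d/", cname))
  }
  pmids <- sort(ls(tx))
  if (!is.null(universe)) {
    missing_pmids <- setdiff(pmids, universe)
    if (length(missing_pmids)) {
      stop("index PMIDs outside the stated universe: ",
           paste(utils::head(missing_pmids, 3), collapse = ", "))
    }
    pmids <- sort(unique(as.character(universe)))
  }
  db <- stats::setNames(lapply(pmids, function(p) {
    sort(unique(get0(p, envir = tx, ifnotfound = character(0))))
  }), pmids)
  structure(db, class = "pm_transactions",
            n_items = length(unique(unlist(db))))
}

#' @export
print.pm_transactions <- function(x, ...) {
  cat(sprintf("<pm_transactions: %d transactions, %d distinct items>\n",
              length(x), attr(x, "n_items")))
  invisible(x)
}

#' Minimum support count implied by a support fraction
#'
#' The smallest integer k with k/N >= sup, i.e. `ceiling(sup * N)`, floored
#' at 1.  At the default mining support of 2.5e-7 and a corpus of about 7
#' million transactions this evaluates to 2 documents.
#'
#' @param sup Support fraction in (0, 1].
#' @param N Transaction count (>= 1).
#' @return Integer support count.
#' @export
min_support_count <- function(sup, N) {
  stopifnot(N >= 1, sup >= 0, sup <= 1)
  k <- as.integer(ceiling(sup * N - 1e-9))
  if (k < 1L) k <- 1L
  while (k / N < sup) k <- k + 1L  # guard against float rounding
  k
}

#' Mining parameters
#'
#' Defaults reproduce the reference mining configuration: minimum support
#' 2.5e-7 (two documents at a ~7M-document corpus), minimum confidence 0.1,
#' rules of exactly two items, and a minimum phenotype document frequency of
#' 10 applied upstream.
#'
#' @param sup Minimum support fraction.
#' @param conf Minimum rule confidence.
#' @param minlen,maxlen Itemset cardinality bounds (>= 2).
#' @param min_phenotype_df Documented upstream filter (not applied here).
#' @return A list of class `pm_apriori_params`.
#' @export
apriori_params <- function(sup = 0.00000025, conf = 0.1,
                           minlen = 2L, maxlen = 2L, min_phenotype_df = 10L) {
  stopifnot(sup > 0, sup <= 1, conf >= 0, conf <= 1,
            minlen >= 2L, minlen <= maxlen)
  structure(list(sup = sup, conf = conf, minlen = as.integer(minlen),
                 maxlen = as.integer(maxlen),
                 min_phenotype_df = as.integer(min_phenotype_df)),
            class = "pm_apriori_params")
}

itemset_key <- function(items) paste(sort(items), collapse = "\x1f")

# level-wise frequent itemset mining; returns named numeric vector
# key -> support count, for itemsets of size 1..maxlen
frequent_itemsets <- function(db, minsup_count, maxlen) {
  counts1 <- table(unlist(db, use.names = FALSE))
  L1 <- names(counts1)[counts1 >= minsup_count]
  supports <- as.list(stats::setNames(as.numeric(counts1[L1]), L1))
  db_f <- lapply(db, function(t) sort(intersect(t, L1)))
  level <- lapply(L1, identity)  # list of sorted item vectors
  k <- 1L
  while (k < maxlen && length(level) > 0L) {
    k <- k + 1L
    # candidate generation: join (k-1)-sets sharing a (k-2)-prefix,
    # then prune candidates with an infrequent subset
    prev_keys <- vapply(level, itemset_key, character(1))
    cand <- list()
    seen <- new.env(parent = emptyenv())
    for (i in seq_along(level)) for (j in seq_along(level)) {
      if (i >= j) next
      a <- level[[i]]; b <- level[[j]]
      if (k > 2L && !identical(a[seq_len(k - 2L)], b[seq_len(k - 2L)])) next
      u <- sort(union(a, b))
      if (length(u) != k) next
      key <- itemset_key(u)
      if (!is.null(get0(key, envir = seen))) next
      # subset pruning
      subs_ok <- all(vapply(seq_len(k), function(d) {
        itemset_key(u[-d]) %in% prev_keys
      }, logical(1)))
      if (!subs_ok) next
      assign(key, TRUE, envir = seen)
      cand[[length(cand) + 1L]] <- u
    }
    if (length(cand) == 0L) break
    cand_keys <- vapply(cand, itemset_key, character(1))
    counts <- stats::setNames(numeric(length(cand)), cand_keys)
    cand_pos <- new.env(parent = emptyenv())
    for (ci in seq_along(cand_keys)) assign(cand_keys[ci], ci, envir = cand_pos)
    for (t in db_f) {
      if (length(t) < k) next
      if (choose(length(t), k) <= 4L * length(cand)) {
        # enumerate the transaction's own k-subsets (fast for short baskets)
        for (s in utils::combn(t, k, simplify = FALSE)) {
          ci <- get0(itemset_key(s), envir = cand_pos)
          if (!is.null(ci)) counts[ci] <- counts[ci] + 1
        }
      } else {
        for (ci in seq_along(cand)) {
          if (all(cand[[ci]] %in% t)) counts[ci] <- counts[ci] + 1
        }
      }
    }
    keep <- counts >= minsup_count
    level <- cand[keep]
    for (key in names(counts)[keep]) supports[[key]] <- counts[[key]]
  }
  supports
}

rules_frame <- function(antecedent, consequent, a, b, c, d, N) {
  support_count <- a
  df <- data.frame(
    antecedent = antecedent, consequent = consequent,
    a = a, b = b, c = c, d = d,
    support_count = support_count,
    support = if (length(a)) support_count / N else numeric(0),
    confidence = if (length(a)) a / (a + b) else numeric(0),
    p_value = if (length(a)) fisher_p(a, b, c, d) else numeric(0),
    stringsAsFactors = FALSE)
  class(df) <- c("pm_rules", "data.frame")
  attr(df, "N") <- N
  df
}

#' @export
print.pm_rules <- function(x, ...) {
  cat(sprintf("<pm_rules: %d rules over N = %s transactions>\n",
              nrow(x), format(attr(x, "N"))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Mine phenotype-disorder association rules with Apriori
#'
#' Level-wise frequent-itemset mining with support-based candidate pruning up
#' to `maxlen`, followed by rule generation (single-item consequent, as in
#' the arules implementation) at confidence >= `conf`, and a type
#' post-filter keeping only rules whose antecedent items are all `p/`
#' phenotypes and whose consequent is a `d/` disorder.  Each surviving rule
#' carries its 2x2 contingency table over the N transactions
#' (a = antecedent and consequent, b = antecedent only, c = consequent only,
#' d = neither) and the one-sided Fisher's exact p-value used for ranking.
#'
#' @param db A `pm_transactions` database (see [build_transactions()]).
#' @param params An [apriori_params()] list.
#' @return A `pm_rules` data frame sorted as produced (use [rank_rules()]
#'   for p-value ranking); attribute `N` is the transaction count.
#' @export
apriori <- function(db, params = apriori_params()) {
  N <- length(db)
  if (N == 0L) stop("empty transaction database: nothing to mine")
  minsup <- min_support_count(params$sup, N)
  supports <- frequent_itemsets(db, minsup, params$maxlen)
  keys <- names(supports)
  if (is.null(keys)) keys <- character(0)
  sizes <- lengths(strsplit(keys, "\x1f", fixed = TRUE))

  ant <- character(0); cons <- character(0)
  a <- numeric(0); b <- numeric(0); cc <- numeric(0); dd <- numeric(0)
  for (key in keys[sizes >= params$minlen & sizes <= params$maxlen]) {
    items <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    supp_s <- supports[[key]]
    for (ci in seq_along(items)) {
      consequent <- items[ci]
      antecedent <- items[-ci]
      supp_ant <- supports[[itemset_key(antecedent)]]
      conf <- supp_s / supp_ant
      if (conf < params$conf) next
      if (!all(startsWith(antecedent, "p/")) || !startsWith(consequent, "d/")) next
      supp_cons <- supports[[consequent]]
      if (is.null(supp_cons)) {
        # consequent frequent by anti-monotonicity; count defensively
        supp_cons <- sum(vapply(db, function(t) consequent %in% t, logical(1)))
      }
      ant <- c(ant, paste(antecedent, collapse = ","))
      cons <- c(cons, consequent)
      a <- c(a, supp_s)
      b <- c(b, supp_ant - supp_s)
      cc <- c(cc, supp_cons - supp_s)
      dd <- c(dd, N - supp_ant - supp_cons + supp_s)
    }
  }
  rules_frame(ant, cons, a, b, cc, dd, N)
}

#' Brute-force rule-mining oracle
#'
#' Independent verification oracle for [apriori()]: enumerates every itemset
#' of size up to `maxlen` over the distinct items (no pruning), counts
#' supports by direct scans, and generates rules by definition.  Intended for
#' small databases only.
#'
#' @inheritParams apriori
#' @param max_items Guard on the number of distinct items (default 15).
#' @return A `pm_rules` data frame.
#' @export
brute_force_rules <- function(db, params = apriori_params(), max_items = 15L) {
  N <- length(db)
  if (N == 0L) stop("empty transaction database: nothing to mine")
  items <- sort(unique(unlist(db, use.names = FALSE)))
  if (length(items) > max_items) stop("brute_force_rules: too many items")
  minsup <- min_support_count(params$sup, N)
  count_set <- function(s) sum(vapply(db, function(t) all(s %in% t), logical(1)))

  ant <- character(0); cons <- character(0)
  a <- numeric(0); b <- numeric(0); cc <- numeric(0); dd <- numeric(0)
  for (k in seq(params$minlen, min(params$maxlen, length(items)))) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (s in combos) {
      supp_s <- count_set(s)
      if (supp_s < minsup) next
      for (ci in seq_along(s)) {
        consequent <- s[ci]
        antecedent <- s[-ci]
        supp_ant <- count_set(antecedent)
        if (supp_ant < minsup) next  # antecedent must itself be frequent
        conf <- supp_s / supp_ant
        if (conf < params$conf) next
        if (!all(startsWith(antecedent, "p/")) || !startsWith(consequent, "d/")) next
        supp_cons <- count_set(consequent)
        ant <- c(ant, paste(sort(antecedent), collapse = ","))
        cons <- c(cons, consequent)
        a <- c(a, supp_s)
        b <- c(b, supp_ant - supp_s)
        cc <- c(cc, supp_cons - supp_s)
        dd <- c(dd, N - supp_ant - supp_cons + supp_s)
      }
    }
  }
  rules_frame(ant, cons, a, b, cc, dd, N)
}

#' One-sided Fisher's exact p-value for a 2x2 table
#'
#' Probability of observing `a` or more co-occurrences under the
#' hypergeometric null with the table's margins fixed (the
#' over-representation tail), i.e. the p-value that ranks enriched
#' phenotype-disorder pairs first.  Vectorized over the four counts.
#'
#' @param a Documents containing both items.
#' @param b Documents with the antecedent only.
#' @param c Documents with the consequent only.
#' @param d Documents with neither.
#' @return P-values in `[0, 1]`.
#' @export
fisher_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("contingency counts must be non-negative")
  stopifnot(all(a + b + c + d >= 1))
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Hypergeometric enumeration oracle for [fisher_p()]
#'
#' Sums the hypergeometric point probabilities for every achievable table
#' with co-occurrence count at least `a`, computed from log binomial
#' coefficients.  Small tables only.
#'
#' @inheritParams fisher_p
#' @return A single p-value.
#' @export
fisher_p_oracle <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, all(c(a, b, c, d) >= 0), a + b + c + d >= 1)
  N <- a + b + c + d
  m <- a + b      # antecedent margin
  k <- a + c      # consequent margin
  ks <- seq(max(0L, k - (N - m)), min(m, k))
  ks <- ks[ks >= a]
  if (length(ks) == 0L) return(0)
  sum(exp(lchoose(m, ks) + lchoose(N - m, k - ks) - lchoose(N, k)))
}

#' Rank rules by p-value
#'
#' Ascending p-value; ties broken by descending support count, then by
#' antecedent lexicographically.
#'
#' @param rules A `pm_rules` frame.
#' @return The rules reordered.
#' @export
rank_rules <- function(rules) {
  ord <- order(rules$p_value, -rules$support_count, rules$antecedent)
  rules[ord, , drop = FALSE]
}

#' Summary statistics over a rule set
#'
#' @param rules A non-empty `pm_rules` frame.
#' @return List with mean/median/max support count and confidence.
#' @export
summarize_rules <- function(rules) {
  if (nrow(rules) == 0L) stop("no rules to summarize")
  list(mean_support_count = mean(rules$support_count),
       median_support_count = stats::median(rules$support_count),
       max_support_count = max(rules$support_count),
       mean_confidence = mean(rules$confidence),
       median_confidence = stats::median(rules$confidence),
       max_confidence = max(rules$confidence))
}

#' Benjamini-Hochberg adjusted p-values (optional extra)
#'
#' Adds a `p_adjust` column (BH).  The reference workflow ranks raw
#' p-values; this column is an optional convenience, not part of it.
#'
#' @param rules A `pm_rules` frame.
#' @return The rules with a `p_adjust` column.
#' @export
adjust_rules <- function(rules) {
  rules$p_adjust <- stats::p.adjust(rules$p_value, method = "BH")
  rules
}

#' Write rules to TSV
#'
#' Columns: antecedent, consequent, a, b, c, d, support, confidence,
#' p_value (and p_adjust when present).
#'
#' @param rules A `pm_rules` frame.
#' @param path Output file.
#' @export
write_rules <- function(rules, path) {
  cols <- intersect(c("antecedent", "consequent", "a", "b", "c", "d",
                      "support", "confidence", "p_value", "p_adjust"),
                    names(rules))
  utils::write.table(as.data.frame(rules)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
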