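# shared test utilities: canonical binding sets, tiny corpora, random
# transaction databases

# order-independent canonical form of a match result list
binding_set <- function(matches) {
  sort(vapply(matches, function(m) paste(m$bindings, collapse = ","), character(1)))
}

expect_match_equiv <- function(pattern, tree) {
  expect_identical(binding_set(match_pattern(pattern, tree)),
                   binding_set(brute_force_match(pattern, tree)))
}

# annotated tree for "a large dilated esophagus" (the classic example)
example_esophagus_tree <- function(lexicons = gen_lexicons()) {
  tree <- read_ptb("(NP (DT a) (JJ large) (JJ dilated) (NN esophagus))")
  assemble_semantic_tree(tree, annotate(tree_yield(tree), lexicons))
}

# write a small lexicon TSV and return its path
write_lexicon_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("term\tconcept_id\tnamespace", rows), path)
  path
}

# random small transaction database over p/ and d/ items
random_db <- function(seed, max_items = 12L, max_tx = 200L) {
  set.seed(seed)
  n_p <- sample(2:6, 1)
  n_d <- sample(2:(max_items - 6), 1)
  items <- c(paste0("p/ph", seq_len(n_p)), paste0("d/dis", seq_len(n_d)))
  n_tx <- sample(5:max_tx, 1)
  db <- lapply(seq_len(n_tx), function(i) {
    k <- sample(0:min(5, length(items)), 1)
    sort(sample(items, k))
  })
  names(db) <- as.character(seq_len(n_tx) + 1e6)
  structure(db, class = "pm_transactions", n_items = length(items))
}

rules_canonical <- function(rules) {
  df <- as.data.frame(rules)[, c("antecedent", "consequent", "a", "b", "c",
                                 "d", "support", "confidence")]
  df <- df[order(df$antecedent, df$consequent), ]
  rownames(df) <- NULL
  df
}
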