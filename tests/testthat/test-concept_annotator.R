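test_that("TSV lexicons load, deduplicate, and reject malformed rows", {
  path <- write_lexicon_tsv(c("nerve\tFMA:65132\tFMA",
                              "nerve\tFMA:65132\tFMA",
                              "median nerve\tFMA:14385\tFMA"))
  lex <- load_lexicon(path, "tsv")
  expect_identical(lex$namespace, "FMA")
  expect_identical(lex$entries[["nerve"]], "FMA:65132")  # dedup is silent
  expect_identical(lex$entries[["median nerve"]], "FMA:14385")

  bad <- write_lexicon_tsv(c("nerve\tFMA:65132\tFMA", "only-one-column"))
  expect_error(load_lexicon(bad, "tsv"), "line 3")
})

test_that("OBO lexicons include names and exact synonyms", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: FMA:7131", "name: esophagus",
               'synonym: "gullet" EXACT []',
               'synonym: "oesophagus" RELATED []', "",
               "[Typedef]", "id: part_of"), path)
  lex <- load_lexicon(path, "obo", namespace = "FMA")
  expect_identical(lex$entries[["esophagus"]], "FMA:7131")
  expect_identical(lex$entries[["gullet"]], "FMA:7131")
  expect_null(lex$entries[["oesophagus"]])  # non-exact synonym excluded
})

test_that("namespace hygiene is enforced", {
  expect_error(lexicon("F/MA"), "namespace")
  expect_error(lexicon("fma"), "namespace")
})

test_that("annotation finds per-namespace hits independently", {
  pato <- lexicon("PATO", c("median", "thickened"), c("PATO:1", "PATO:2"))
  fma <- lexicon("FMA", "nerve", "FMA:65132")
  ann <- annotate(c("the", "median", "nerve"), list(pato, fma))
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$token_start, c(1L, 2L))
  expect_identical(ann$token_end, c(2L, 3L))
  expect_identical(ann$namespace, c("PATO", "FMA"))

  expect_identical(nrow(annotate(c("no", "hits", "here"), list(pato))), 0L)
  # case-invariant
  ann2 <- annotate(c("THE", "Median", "NERVE"), list(pato, fma))
  expect_identical(ann2[, 1:3], ann[, 1:3])
  # fixture PATO lexicon annotates the worked-example adjective
  expect_identical(annotate("thickened", gen_lexicons()["PATO"])$namespace, "PATO")
})

test_that("longest match wins within a namespace", {
  fma <- lexicon("FMA", c("nerve", "median nerve"), c("FMA:65132", "FMA:14385"))
  ann <- annotate(c("median", "nerve"), list(fma))
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$concept_id, "FMA:14385")
  expect_identical(c(ann$token_start, ann$token_end), c(0L, 2L))
})

# independent oracle: enumerate every matching span, then select
# leftmost-longest non-overlapping spans per namespace
annotate_oracle <- function(tokens, lex) {
  low <- tolower(tokens)
  spans <- list()
  for (s in seq_along(low)) for (e in seq(s, length(low))) {
    key <- paste(low[s:e], collapse = " ")
    if (!is.null(lex$entries[[key]])) {
      spans[[length(spans) + 1L]] <- c(s, e)
    }
  }
  chosen <- list()
  taken <- rep(FALSE, length(low))
  while (length(spans)) {
    starts <- vapply(spans, `[[`, numeric(1), 1)
    lens <- vapply(spans, function(x) x[2] - x[1], numeric(1))
    ord <- order(starts, -lens)
    sp <- spans[[ord[1]]]
    spans <- spans[-ord[1]]
    if (any(taken[sp[1]:sp[2]])) next
    taken[sp[1]:sp[2]] <- TRUE
    chosen[[length(chosen) + 1L]] <- sp
  }
  chosen
}

test_that("greedy matching equals the exhaustive span-enumeration oracle", {
  set.seed(31)
  vocab <- c("alpha", "beta", "gamma", "delta", "eps")
  for (rep in 1:40) {
    n_terms <- sample(3:8, 1)
    terms <- unique(vapply(seq_len(n_terms), function(i) {
      paste(sample(vocab, sample(1:2, 1)), collapse = " ")
    }, character(1)))
    lex <- lexicon("HP", terms, sprintf("HP:%07d", seq_along(terms)))
    tokens <- sample(vocab, sample(3:9, 1), replace = TRUE)
    got <- annotate(tokens, list(lex))
    want <- annotate_oracle(tokens, lex)
    got_spans <- unique(Map(c, got$token_start + 1L, got$token_end))
    expect_identical(lapply(got_spans, as.numeric),
                     lapply(want, as.numeric),
                     info = paste(tokens, collapse = " "))
  }
})

test_that("annotated spans never overlap within one namespace", {
  lexicons <- gen_lexicons()
  corp <- gen_corpus(fixture_config(seed = 5L, n_sentences = 40L), lexicons)
  for (s in corp$sentences$ptb_tree[1:10]) {
    toks <- tree_yield(read_ptb(s))
    ann <- annotate(toks, lexicons)
    for (ns in unique(ann$namespace)) {
      a <- ann[ann$namespace == ns, ]
      a <- a[!duplicated(a[, c("token_start", "token_end")]), ]
      if (nrow(a) < 2) next
      a <- a[order(a$token_start), ]
      expect_true(all(a$token_start[-1] >= a$token_end[-nrow(a)]))
    }
    expect_true(all(ann$token_end <= length(toks)))
  }
})

test_that("semantic tree assembly projects spans and is reversible", {
  tree <- read_ptb("(NP (DT a) (JJ large) (NN esophagus))")
  ann <- data.frame(token_start = c(1L, 2L), token_end = c(2L, 3L),
                    namespace = c("PATO", "FMA"),
                    concept_id = c("PATO:0000586", "FMA:7131"))
  at <- assemble_semantic_tree(tree, ann)
  expect_identical(
    write_ptb(at),
    "(NP (DT a) (JJ large (SEM PATO:0000586)) (NN esophagus (SEM FMA:7131)))")
  # word yield unchanged, SEM excluded
  expect_identical(tree_yield(at), tree_yield(tree))
  # stripping recovers the original exactly
  expect_true(tree_equal(strip_sem(at), tree))

  # empty annotation set: identity
  empty <- ann[0, ]
  expect_true(tree_equal(assemble_semantic_tree(tree, empty), tree))

  # multi-token span projects onto every covered preterminal
  ann2 <- data.frame(token_start = 1L, token_end = 3L,
                     namespace = "FMA", concept_id = "FMA:14385")
  at2 <- assemble_semantic_tree(tree, ann2)
  expect_identical(
    write_ptb(at2),
    "(NP (DT a) (JJ large (SEM FMA:14385)) (NN esophagus (SEM FMA:14385)))")

  # out-of-range span is an error
  bad <- data.frame(token_start = 2L, token_end = 4L,
                    namespace = "FMA", concept_id = "x")
  expect_error(assemble_semantic_tree(tree, bad), "out of range")
})

test_that("strip_sem(assemble(t, A)) == t on random annotated trees", {
  trees <- gen_fixture_trees(60, seed = 17L)
  for (t in trees) {
    plain <- strip_sem(t)
    toks <- tree_yield(plain)
    k <- min(2L, length(toks))
    ann <- data.frame(token_start = seq_len(k) - 1L, token_end = seq_len(k),
                      namespace = "PATO",
                      concept_id = sprintf("PATO:%07d", seq_len(k)))
    expect_true(tree_equal(strip_sem(assemble_semantic_tree(plain, ann)), plain))
  }
})
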