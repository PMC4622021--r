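test_that("normalize_term lowercases, strips determiners, collapses spaces", {
  expect_identical(normalize_term("a large dilated esophagus"),
                   "large dilated esophagus")
  expect_identical(normalize_term("Abnormal  Gait"), "abnormal gait")
  expect_identical(normalize_term("The Median Nerve"), "median nerve")
  # idempotence on random strings
  set.seed(41)
  for (i in 1:200) {
    s <- paste(sample(c("A", "an", "THE", "odd", "Gait", " ", "x"),
                      sample(2:6, 1), replace = TRUE), collapse = " ")
    s <- gsub("^\\s+|\\s+$", "", s)
    if (!nzchar(s)) next
    n1 <- normalize_term(s)
    expect_identical(normalize_term(n1), n1)
  }
})

make_sentence <- function(pmid, sent_index, tree_string) {
  sentence_records(pmid, sent_index,
                   paste(tree_yield(read_ptb(tree_string)), collapse = " "),
                   tree_string)
}

esoph_np <- paste0("(S (NP (DT a) (JJ large (SEM PATO:0000586)) ",
                   "(JJ dilated (SEM PATO:0000608)) ",
                   "(NN esophagus (SEM FMA:7131))) ",
                   "(VP (VBD was) (VBN seen)))")

test_that("extraction yields EQ-decomposed candidates with merged provenance", {
  sentences <- rbind(make_sentence("100", 0L, esoph_np),
                     make_sentence("100", 3L, esoph_np),
                     make_sentence("200", 1L, esoph_np))
  cands <- extract_candidates(sentences)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$pm_id, "PM1")
  expect_identical(cands$surface, "a large dilated esophagus")
  expect_identical(cands$normalized, "large dilated esophagus")
  expect_identical(cands$qualities[[1]], c("PATO:0000586", "PATO:0000608"))
  expect_identical(cands$entities[[1]], "FMA:7131")
  src <- cands$sources[[1]]
  expect_identical(nrow(src), 3L)                 # 3 sentences merged
  expect_identical(sort(unique(src$pmid)), c("100", "200"))
  expect_identical(unique(src$pattern_id), "p1")
})

test_that("zero-match corpora produce empty candidate frames", {
  s <- make_sentence("1", 0L, "(S (NP (DT the) (NN liver)) (VP (VBD was)))")
  cands <- extract_candidates(s)
  expect_identical(nrow(cands), 0L)
})

test_that("every fixture-corpus candidate satisfies EQ completeness", {
  corp <- gen_corpus(fixture_config(seed = 19L, n_sentences = 120L))
  cands <- extract_candidates(corp$sentences)
  expect_gt(nrow(cands), 0L)
  expect_true(all(lengths(cands$qualities) >= 1L))
  expect_true(all(lengths(cands$entities) >= 1L))
  # accessions are dense and first-occurrence ordered
  expect_identical(cands$pm_id, paste0("PM", seq_len(nrow(cands))))
})

toy_candidates <- function(terms) {
  sentences <- do.call(rbind, lapply(seq_along(terms), function(i) {
    make_sentence(as.character(i), 0L, sprintf(
      "(S (NP (DT a) (JJ odd (SEM PATO:%07d)) (NN %s (SEM FMA:%07d))) (VP (VBD was)))",
      i, terms[i], i))
  }))
  extract_candidates(sentences)
}

test_that("df filtering is inclusive at the threshold and order-preserving", {
  terms <- c("t0", "t5", "t9", "t10", "t25", "tmax")
  cands <- toy_candidates(terms)
  dfs <- c(0L, 5L, 9L, 10L, 25L, 10000L)
  idx <- document_index(
    paste("odd", terms)[dfs > 0],
    lapply(dfs[dfs > 0], function(k) as.character(seq_len(k))))
  kept <- filter_by_df(cands, idx, min_df = 10L)
  expect_identical(nrow(kept), 3L)
  expect_identical(kept$normalized, paste("odd", c("t10", "t25", "tmax")))
  expect_identical(kept$df, c(10L, 25L, 10000L))
  expect_identical(vapply(kept$df_pmids, length, integer(1)), kept$df)

  # min_df = 0 keeps everything, including index misses (df = 0)
  all_kept <- filter_by_df(cands, idx, min_df = 0L)
  expect_identical(nrow(all_kept), nrow(cands))
})

test_that("df stratification reproduces hand counts and printed shares", {
  dfs <- c(rep(0L, 10), rep(1L, 5), rep(12L, 4), rep(30L, 3), rep(20000L, 2))
  tab <- stratify_df(dfs)
  expect_identical(tab$count, c(14L, 9L, 5L, 2L))
  expect_identical(tab$pct, round(100 * c(14, 9, 5, 2) / 24, 1))

  # the published corpus shares follow from the printed counts
  pub <- c(rep(20000L, 281), rep(25L, 8033 - 281), rep(10L, 9792 - 8033),
           rep(1L, 12747 - 9792), rep(0L, 13636 - 12747))
  tab2 <- stratify_df(pub)
  expect_identical(tab2$count, c(12747L, 9792L, 8033L, 281L))
  expect_identical(tab2$pct[tab2$threshold == 1L], 93.5)
  expect_identical(tab2$pct[tab2$threshold == 25L], 58.9)
  expect_identical(tab2$pct[tab2$threshold == 10000L], 2.1)

  empty <- stratify_df(integer(0))
  expect_true(all(empty$count == 0L) && all(empty$pct == 0))
})

test_that("XML export validates, embeds rules, and round-trips", {
  cands <- toy_candidates(c("gaitx", "liverx"))
  idx <- document_index(cands$normalized,
                        list(as.character(1:12), as.character(1:15)))
  cands <- filter_by_df(cands, idx, 10L)
  rules <- phenomine:::rules_frame(
    antecedent = paste0("p/", cands$normalized[1]),
    consequent = "d/Alpha syndrome",
    a = 7, b = 5, c = 3, d = 85, N = 100L)
  path <- tempfile(fileext = ".xml")
  export_records(cands, rules, path, date = "2026-01-01")
  expect_true(validate_records(path))

  back <- import_records(path)
  expect_identical(back$pm_id, cands$pm_id)
  expect_identical(back$surface, cands$surface)
  expect_identical(back$normalized, cands$normalized)
  expect_identical(back$qualities, cands$qualities)
  expect_identical(back$entities, cands$entities)
  expect_identical(back$df, cands$df)
  expect_identical(back$df_pmids, cands$df_pmids)

  doc <- xml2::read_xml(path)
  dis <- xml2::xml_find_all(doc, "phenotype[1]/disorders/disorder")
  expect_length(dis, 1L)
  expect_identical(xml2::xml_attr(dis, "name"), "Alpha syndrome")
  expect_identical(xml2::xml_attr(dis, "supportCount"), "7")
  # candidate without rules gets an empty disorders element
  expect_length(xml2::xml_find_all(doc, "phenotype[2]/disorders/*"), 0L)

  # dangling rule reference is an error naming the rule
  bad <- phenomine:::rules_frame("p/nonexistent term", "d/X", 1, 1, 1, 1, 4L)
  expect_error(export_records(cands, bad, tempfile(), date = "2026-01-01"),
               "nonexistent term")
})

test_that("JSONL export mirrors the record fields", {
  cands <- toy_candidates("gaity")
  path <- tempfile(fileext = ".jsonl")
  export_records(cands, phenomine:::empty_rules(), path, format = "jsonl",
                 date = "2026-01-01")
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_identical(rec$pm_id, "PM1")
  expect_identical(rec$term, "odd gaity")
  expect_identical(rec$annotated, "2026-01-01")
})
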