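test_that("MEDIC loading keeps only OMIM-identified disorders", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "DiseaseName\tDiseaseID\tAltDiseaseIDs\tSynonyms",
    "Marfan Syndrome\tMESH:D008382\tOMIM:154700\tMarfan's syndrome|MFS",
    "Common Cold\tMESH:D003139\t\t",
    "Leopard Syndrome\tOMIM:151100\t\tGorlin syndrome|Cardiocutaneous syndrome"),
    path)
  vocab <- read_medic(path)
  expect_identical(nrow(vocab), 2L)
  expect_identical(vocab$omim_id, c("OMIM:154700", "OMIM:151100"))
  expect_identical(vocab$synonyms[[1]], c("Marfan's syndrome", "MFS"))
})

test_that("transactions unify synonym PMIDs under the canonical disorder", {
  vocab <- disorder_vocabulary(
    "Leopard syndrome", "OMIM:151100",
    list(c("Gorlin syndrome", "Cardiocutaneous syndrome")))
  didx <- document_index(
    c("Leopard syndrome", "Gorlin syndrome", "Cardiocutaneous syndrome"),
    list(c("1", "2"), c("2", "3"), "4"))
  pidx <- document_index("abnormal gait", list(c("2", "9")))
  db <- build_transactions(pidx, vocab, didx)
  expect_setequal(names(db)[vapply(db, function(t)
    "d/Leopard syndrome" %in% t, logical(1))], c("1", "2", "3", "4"))
  expect_identical(db[["2"]], c("d/Leopard syndrome", "p/abnormal gait"))
  expect_identical(db[["9"]], "p/abnormal gait")  # singleton kept, counts in N
  expect_identical(length(db), 5L)
})

test_that("one PMID under one disorder and five phenotypes gives a 6-item transaction", {
  vocab <- disorder_vocabulary("Marfan Syndrome", "OMIM:154700")
  didx <- document_index("Marfan Syndrome", list("18852161"))
  phenos <- paste("abnormal", c("chest signs", "connective tissue",
                                "connective tissue structure",
                                "tissue pathology", "weight control"))
  pidx <- document_index(phenos, rep(list("18852161"), 5))
  db <- build_transactions(pidx, vocab, didx)
  expect_length(db, 1L)
  expect_length(db[["18852161"]], 6L)
  expect_identical(sum(startsWith(db[["18852161"]], "d/")), 1L)
})

test_that("ambiguous synonyms are an error unless overridden", {
  vocab <- disorder_vocabulary(c("A syndrome", "B syndrome"),
                               c("OMIM:1", "OMIM:2"),
                               list("shared name", "shared name"))
  didx <- document_index(c("A syndrome", "B syndrome", "shared name"),
                         list("1", "2", "3"))
  pidx <- document_index(character(0), list())
  expect_error(build_transactions(pidx, vocab, didx),
               "shared name.*A syndrome / B syndrome")
  db <- build_transactions(pidx, vocab, didx, on_ambiguous_synonym = "both")
  expect_identical(db[["3"]], c("d/A syndrome", "d/B syndrome"))
})

test_that("min_support_count is the ceiling floored at one", {
  expect_identical(min_support_count(0.00000025, 7e6), 2L)
  expect_identical(min_support_count(0, 1000), 1L)
  expect_identical(min_support_count(0.5, 5), 3L)
  expect_identical(min_support_count(1, 8), 8L)
})

five_tx_db <- function() {
  db <- list(`1` = c("d/X", "p/A"), `2` = c("d/X", "p/A"), `3` = "p/A",
             `4` = "d/X", `5` = "p/B")
  structure(db, class = "pm_transactions", n_items = 3L)
}

test_that("apriori mines the worked example correctly", {
  rules <- apriori(five_tx_db(), apriori_params(sup = 0.2, conf = 0.1))
  expect_identical(nrow(rules), 1L)
  expect_identical(rules$antecedent, "p/A")
  expect_identical(rules$consequent, "d/X")
  expect_identical(rules$support_count, 2)
  expect_identical(rules$support, 0.4)
  expect_equal(rules$confidence, 2 / 3)
  expect_identical(c(rules$a, rules$b, rules$c, rules$d), c(2, 1, 1, 1))

  # unattainable confidence yields no rules
  none <- apriori(five_tx_db(), apriori_params(sup = 0.2, conf = 1.0))
  expect_identical(nrow(none), 0L)

  expect_error(apriori(structure(list(), class = "pm_transactions")),
               "empty transaction")
})

test_that("apriori equals brute-force enumeration on random databases", {
  for (seed in 1:30) {
    db <- random_db(seed)
    params <- apriori_params(sup = sample(c(0.005, 0.02, 0.1), 1),
                             conf = sample(c(0.05, 0.2, 0.5), 1))
    expect_identical(rules_canonical(apriori(db, params)),
                     rules_canonical(brute_force_rules(db, params)),
                     info = paste("seed", seed))
  }
})

test_that("the level-wise general case agrees with brute force at maxlen 3", {
  for (seed in 31:40) {
    db <- random_db(seed, max_tx = 60L)
    params <- apriori_params(sup = 0.02, conf = 0.1, minlen = 2L, maxlen = 3L)
    expect_identical(rules_canonical(apriori(db, params)),
                     rules_canonical(brute_force_rules(db, params)),
                     info = paste("seed", seed))
  }
})

test_that("support anti-monotonicity holds for mined rules", {
  db <- random_db(99)
  params <- apriori_params(sup = 0.02, conf = 0)
  rules <- apriori(db, params)
  minsup <- min_support_count(params$sup, length(db))
  item_count <- function(item) sum(vapply(db, function(t) item %in% t, logical(1)))
  for (i in seq_len(nrow(rules))) {
    expect_gte(item_count(rules$antecedent[i]), minsup)
    expect_gte(item_count(rules$consequent[i]), minsup)
  }
})

test_that("fisher_p matches closed forms and the enumeration oracle", {
  expect_equal(fisher_p(5, 0, 0, 5), 1 / choose(10, 5), tolerance = 1e-12)
  expect_identical(fisher_p(0, 5, 5, 90), 1)  # minimal attainable overlap

  set.seed(77)
  for (i in 1:300) {
    n <- sample(1:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = rep(0.25, 4)))
    p1 <- fisher_p(cells[1], cells[2], cells[3], cells[4])
    p2 <- fisher_p_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_lt(abs(p1 - p2), 1e-12)
    # agrees with stats::fisher.test one-sided greater
    if (all(cells + c(0, 0, 0, 0) >= 0) && n >= 2) {
      ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                               alternative = "greater")$p.value
      expect_equal(p1, ft, tolerance = 1e-9)
    }
  }

  expect_error(fisher_p(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_p is monotone non-increasing in a at fixed margins", {
  N <- 40L; m <- 15L; k <- 12L
  as <- max(0L, m + k - N):min(m, k)
  ps <- vapply(as, function(a) fisher_p(a, m - a, k - a, N - m - k + a),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-14))
})

test_that("rule identities and ranking behave as specified", {
  db <- random_db(7)
  rules <- apriori(db, apriori_params(sup = 0.01, conf = 0))
  N <- attr(rules, "N")
  # confidence * P(antecedent) == support
  expect_equal(rules$confidence * (rules$a + rules$b) / N, rules$support,
               tolerance = 1e-12)
  expect_true(all(rules$a + rules$b + rules$c + rules$d == N))

  r <- phenomine:::rules_frame(
    antecedent = c("p/z", "p/a", "p/m", "p/b"),
    consequent = rep("d/X", 4),
    a = c(3, 10, 10, 5), b = c(1, 2, 2, 1), c = c(1, 1, 1, 1),
    d = c(95, 87, 87, 93), N = 100L)
  r$p_value <- c(0.5, 0.02, 0.02, 0.001)
  ranked <- rank_rules(r)
  expect_identical(ranked$antecedent, c("p/b", "p/a", "p/m", "p/z"))
})

test_that("rule summaries and TSV round-trip", {
  r <- phenomine:::rules_frame("p/a", "d/X", 7, 7, 3, 83, 100L)
  s <- summarize_rules(r)
  expect_identical(s$mean_support_count, 7)
  expect_identical(s$median_confidence, 0.5)

  r2 <- phenomine:::rules_frame(c("p/a", "p/b"), c("d/X", "d/X"),
                                c(10, 20), c(5, 10), c(2, 3), c(83, 67), 100L)
  s2 <- summarize_rules(r2)
  expect_identical(s2$mean_support_count, 15)
  expect_identical(s2$median_support_count, 15)
  expect_identical(s2$max_support_count, 20)
  expect_error(summarize_rules(phenomine:::empty_rules()), "no rules")

  path <- tempfile(fileext = ".tsv")
  write_rules(adjust_rules(r2), path)
  back <- read_rules(path)
  expect_equal(rules_canonical(back), rules_canonical(r2))
})
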