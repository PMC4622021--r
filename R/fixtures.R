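# Seeded generators for every pipeline input: lexicons, annotated sentence
# corpora with gold extraction labels, and document indexes with planted
# phenotype-disorder co-occurrences whose 2x2 tables are recorded exactly.

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Fixture generator configuration
#'
#' The defaults are the package's stated synthetic world: 200 sentences
#' drawn from templates instantiating the nine extraction patterns (72% of
#' sentences, 8% each) plus five distractor families (28%) modeled on real
#' error classes (incomplete phrases lacking an entity, entity without a
#' quality, inverted word order, comma coordination without a conjunction,
#' and unremarkable sentences with no trigger); a 5,000-document index with
#' 5 planted phenotype-disorder pairs, a 0.002 per-document baseline
#' occurrence probability (giving realistic df around 10) and a 0.02 joint
#' probability for planted pairs (10x baseline, around 100 co-occurring
#' documents).
#'
#' @param seed Integer seed; every generator is bit-reproducible given it.
#' @param n_sentences Corpus size for [gen_corpus()].
#' @param pattern_mix Named probability vector over templates `p1`..`p9`,
#'   `d1`..`d5` (normalized internally).
#' @param lexicon_sizes Named integer vector of per-namespace entry counts;
#'   `NULL` keeps the built-in vocabulary sizes.  A namespace set to 0 is
#'   omitted; sizes above the built-in vocabulary are padded with synthetic
#'   terms not used by any template.
#' @param n_docs Documents in the generated indexes.
#' @param n_disorders Disorders in the generated vocabulary.
#' @param n_planted_pairs Phenotype-disorder pairs with boosted
#'   co-occurrence.
#' @param baseline_cooccur_prob Independent per-document occurrence
#'   probability for every term.
#' @param planted_cooccur_prob Joint per-document occurrence probability
#'   added for planted pairs; must exceed the baseline.
#' @return A list of class `pm_fixture_config`.
#' @export
fixture_config <- function(seed = 42L,
                           n_sentences = 200L,
                           pattern_mix = NULL,
                           lexicon_sizes = NULL,
                           n_docs = 5000L,
                           n_disorders = 12L,
                           n_planted_pairs = 5L,
                           baseline_cooccur_prob = 0.002,
                           planted_cooccur_prob = 0.02) {
  if (is.null(pattern_mix)) {
    pattern_mix <- c(stats::setNames(rep(0.08, 9), paste0("p", 1:9)),
                     d1 = 0.07, d2 = 0.07, d3 = 0.06, d4 = 0.04, d5 = 0.04)
  }
  stopifnot(all(pattern_mix >= 0), sum(pattern_mix) > 0,
            baseline_cooccur_prob >= 0, baseline_cooccur_prob <= 1,
            planted_cooccur_prob > baseline_cooccur_prob,
            planted_cooccur_prob <= 1,
            n_docs >= 1L, n_planted_pairs >= 0L)
  structure(list(seed = as.integer(seed), n_sentences = as.integer(n_sentences),
                 pattern_mix = pattern_mix / sum(pattern_mix),
                 lexicon_sizes = lexicon_sizes,
                 n_docs = as.integer(n_docs),
                 n_disorders = as.integer(n_disorders),
                 n_planted_pairs = as.integer(n_planted_pairs),
                 baseline_cooccur_prob = baseline_cooccur_prob,
                 planted_cooccur_prob = planted_cooccur_prob),
            class = "pm_fixture_config")
}

# built-in template vocabulary ------------------------------------------------

# PATO adjectives that themselves carry an abnormality trigger stem
# (plausible "abnormal" synonyms; every positive sentence uses one)
FX_PATO_TRIGGER <- c("abnormal", "aberrant", "defective", "atypical",
                     "unusual", "irregular", "anomalous", "unhealthy",
                     "inactive", "inadequate", "characteristic")
# further PATO qualities without trigger stems
FX_PATO_PLAIN <- c("large", "dilated", "thickened", "median", "long",
                   "short", "enlarged", "reduced", "thin", "swollen")
# trigger-bearing adverbs for ADJP templates (not lexicon terms)
FX_TRIGGER_RB <- c("abnormally", "atypically", "unusually", "irregularly")

FX_ENTITIES <- list(
  FMA = c("esophagus", "nerve", "femur", "liver", "cornea", "retina",
          "aorta", "spleen"),
  MA = c("tail", "whisker", "snout", "forelimb"),
  CHEBI = c("glucose", "ethanol", "cholesterol", "dopamine"),
  RXNORM = c("aspirin", "ibuprofen", "warfarin", "insulin"),
  HP = c("gait", "nystagmus", "clinodactyly", "strabismus"),
  MP = c("polydactyly", "microphthalmia", "hydrocephalus", "kyphosis"),
  DOID = c("glaucoma", "anemia", "dystrophy", "carcinoma"),
  ORDO = c("achondroplasia", "aniridia"),
  OMIM = c("hemophilia", "porphyria"))

# words guaranteed to have no lexicon entry
FX_PLAIN_NOUN <- c("procedure", "approach", "protocol", "outcome", "specimen")
FX_PLAIN_NOUN_PL <- c("burns", "lesions", "wounds", "scars")
FX_PLAIN_ADJ <- c("solid", "venous", "putative", "standard")

FX_ENTITY_GROUPS <- list(g1 = c("FMA", "RXNORM", "CHEBI", "MA"),
                         g2 = c("MP", "HP"),
                         g3 = c("DOID", "ORDO", "OMIM"))

fx_id <- function(ns, i) sprintf("%s:%07d", ns, i)

#' Generate ontology lexicons
#'
#' Builds one lexicon per namespace (PATO plus the nine entity namespaces)
#' from the built-in template vocabulary, padding with synthetic terms when
#' `lexicon_sizes` asks for more entries.  The worked-example terms (large,
#' dilated, thickened, median in PATO; esophagus, nerve in FMA) are always
#' present so that classic example fragments annotate correctly.
#'
#' @param config A [fixture_config()].
#' @return Named list of [lexicon()] objects.
#' @export
gen_lexicons <- function(config = fixture_config()) {
  with_seed(config$seed + 1L, {
    out <- list()
    base <- c(list(PATO = c(FX_PATO_TRIGGER, FX_PATO_PLAIN)), FX_ENTITIES)
    for (ns in names(base)) {
      terms <- base[[ns]]
      want <- if (ns %in% names(config$lexicon_sizes)) {
        config$lexicon_sizes[[ns]]
      } else NULL
      if (!is.null(want)) {
        want <- as.integer(want)
        if (want == 0L) next
        if (want < length(terms)) {
          terms <- terms[seq_len(want)]
        } else if (want > length(terms)) {
          pad <- sprintf("%sxterm%03d", tolower(ns), seq_len(want - length(terms)))
          terms <- c(terms, pad)
        }
      }
      out[[ns]] <- lexicon(ns, terms, fx_id(ns, seq_along(terms)))
    }
    out
  })
}

fx_pick <- function(x) x[sample.int(length(x), 1L)]

# build one template instance; returns list(tree_string, surfaces, patterns)
fx_sentence <- function(template, lex_terms) {
  leaf <- ptree_leaf
  np <- NULL
  surfaces <- character(0)
  patterns <- character(0)
  vp <- ptree("VP", list(leaf("VBD", "was"), leaf("VBN", "observed")))
  if (template %in% c("p1", "p4", "p7")) {
    g <- FX_ENTITY_GROUPS[[match(template, c("p1", "p4", "p7"))]]
    ns <- fx_pick(g)
    ent <- fx_pick(lex_terms[[ns]])
    adj1 <- fx_pick(lex_terms$PATO_TRIGGER)
    kids <- list(leaf("DT", fx_pick(c("a", "the"))), leaf("JJ", adj1))
    if (stats::runif(1) < 0.5) {
      kids <- c(kids, list(leaf("JJ", fx_pick(lex_terms$PATO_PLAIN))))
    }
    kids <- c(kids, list(leaf("NN", ent)))
    np <- ptree("NP", kids)
    patterns <- template
  } else if (template %in% c("p2", "p5", "p8")) {
    g <- FX_ENTITY_GROUPS[[match(template, c("p2", "p5", "p8"))]]
    ns <- fx_pick(g)
    ent <- fx_pick(lex_terms[[ns]])
    adjp <- ptree("ADJP", list(leaf("RB", fx_pick(FX_TRIGGER_RB)),
                               leaf("JJ", fx_pick(lex_terms$PATO_PLAIN))))
    np <- ptree("NP", list(leaf("DT", "a"), adjp, leaf("NN", ent)))
    patterns <- template
  } else if (template %in% c("p3", "p6", "p9")) {
    g <- FX_ENTITY_GROUPS[[match(template, c("p3", "p6", "p9"))]]
    ns <- fx_pick(g)
    ent <- fx_pick(lex_terms[[ns]])
    np1 <- ptree("NP", list(leaf("JJ", fx_pick(lex_terms$PATO_TRIGGER)),
                            leaf("NNS", fx_pick(FX_PLAIN_NOUN_PL))))
    np2 <- ptree("NP", list(leaf("JJ", fx_pick(FX_PLAIN_ADJ)),
                            leaf("NN", ent)))
    np <- ptree("NP", list(np1, leaf("CC", "and"), np2))
    patterns <- template
  } else if (template == "d1") {
    # incomplete phrase: quality with no entity word
    np <- ptree("NP", list(leaf("DT", "a"),
                           leaf("JJ", fx_pick(lex_terms$PATO_TRIGGER)),
                           leaf("NN", fx_pick(FX_PLAIN_NOUN))))
  } else if (template == "d2") {
    # entity with no quality; trigger supplied by a plain "defect" object
    ns <- fx_pick(names(FX_ENTITIES))
    np <- ptree("NP", list(leaf("DT", "the"),
                           leaf("JJ", fx_pick(FX_PLAIN_ADJ)),
                           leaf("NN", fx_pick(lex_terms[[ns]]))))
    vp <- ptree("VP", list(leaf("VBD", "showed"),
                           ptree("NP", list(leaf("DT", "a"),
                                            leaf("NN", "defect")))))
  } else if (template == "d3") {
    # inverted order: entity precedes the quality
    ns <- fx_pick(names(FX_ENTITIES))
    np <- ptree("NP", list(leaf("DT", "the"),
                           leaf("NN", fx_pick(lex_terms[[ns]])),
                           leaf("JJ", fx_pick(lex_terms$PATO_TRIGGER))))
  } else if (template == "d4") {
    # comma coordination: no CC between the conjunct NPs
    ns <- fx_pick(names(FX_ENTITIES))
    np1 <- ptree("NP", list(leaf("JJ", fx_pick(lex_terms$PATO_TRIGGER)),
                            leaf("NNS", fx_pick(FX_PLAIN_NOUN_PL))))
    np2 <- ptree("NP", list(leaf("JJ", fx_pick(FX_PLAIN_ADJ)),
                            leaf("NN", fx_pick(lex_terms[[ns]]))))
    np <- ptree("NP", list(np1, leaf(",", ","), np2))
  } else if (template == "d5") {
    # no trigger, nothing abnormal
    np <- ptree("NP", list(leaf("DT", "the"), leaf("JJ", "normal"),
                           leaf("NN", fx_pick(FX_PLAIN_NOUN))))
    vp <- ptree("VP", list(leaf("VBD", "appeared"), leaf("JJ", "intact")))
  } else {
    stop("unknown template: ", template)
  }
  tree <- ptree("S", list(np, vp, leaf(".", ".")))
  if (startsWith(template, "p")) {
    surfaces <- paste(tree_yield(np), collapse = " ")
  }
  list(tree = tree, surfaces = surfaces, patterns = patterns)
}

#' Generate an annotated sentence corpus with gold labels
#'
#' Samples templates according to `config$pattern_mix`, instantiates them
#' with seeded vocabulary draws, annotates the trees against the generated
#' lexicons, and records gold labels: the exact surface forms a correct
#' extractor must produce (positives) or the absence of any candidate
#' (distractors).  Every positive sentence contains a trigger stem.
#'
#' @param config A [fixture_config()].
#' @param lexicons Output of [gen_lexicons()] (regenerated if missing).
#' @return List with `sentences` (annotated sentence data frame, about three
#'   sentences per PMID) and `gold` (data frame with `template` and list
#'   columns `surfaces`, `patterns` per sentence).
#' @export
gen_corpus <- function(config = fixture_config(), lexicons = NULL) {
  if (is.null(lexicons)) lexicons <- gen_lexicons(config)
  lex_terms <- lapply(FX_ENTITIES, function(x) x)
  # restrict template draws to terms present in the (possibly resized) lexicons
  for (ns in names(FX_ENTITIES)) {
    have <- names(lexicons[[ns]]$entries)
    lex_terms[[ns]] <- intersect(FX_ENTITIES[[ns]], have)
    if (length(lex_terms[[ns]]) == 0L) {
      stop("lexicon for ", ns, " too small to instantiate templates")
    }
  }
  pato_have <- names(lexicons$PATO$entries)
  lex_terms$PATO_TRIGGER <- intersect(FX_PATO_TRIGGER, pato_have)
  lex_terms$PATO_PLAIN <- intersect(FX_PATO_PLAIN, pato_have)
  stopifnot(length(lex_terms$PATO_TRIGGER) > 0L,
            length(lex_terms$PATO_PLAIN) > 0L)

  with_seed(config$seed + 2L, {
    n <- config$n_sentences
    tmpl <- sample(names(config$pattern_mix), n, replace = TRUE,
                   prob = config$pattern_mix)
    trees <- character(n)
    surfaces <- vector("list", n)
    pats <- vector("list", n)
    for (i in seq_len(n)) {
      s <- fx_sentence(tmpl[i], lex_terms)
      ann <- assemble_semantic_tree(
        s$tree, annotate(tree_yield(s$tree), lexicons))
      trees[i] <- write_ptb(ann)
      surfaces[[i]] <- s$surfaces
      pats[[i]] <- s$patterns
    }
    sentences <- sentence_records(
      pmid = as.character(20000000L + (seq_len(n) - 1L) %/% 3L),
      sent_index = (seq_len(n) - 1L) %% 3L,
      text = vapply(trees, function(t) {
        paste(tree_yield(read_ptb(t)), collapse = " ")
      }, character(1), USE.NAMES = FALSE),
      ptb_tree = trees)
    gold <- data.frame(template = tmpl, stringsAsFactors = FALSE)
    gold$surfaces <- surfaces
    gold$patterns <- pats
    list(sentences = sentences, gold = gold)
  })
}

#' Generate document indexes with planted associations
#'
#' Every document contains every term independently with the baseline
#' probability; for each planted (phenotype, disorder) pair a joint
#' indicator with the planted probability is OR-ed into both columns, the
#' simplest model under which Fisher's exact test is calibrated.  Planted
#' pairs link phenotype i to disorder i.  Each disorder's document hits are
#' partitioned across its canonical name and 1-3 synonyms to exercise
#' synonym unification; per-term PMID lists are capped at the index cap.
#' Gold 2x2 tables are counted from the realized incidence, so they are
#' exact by construction and always sum to `n_docs`.
#'
#' @param config A [fixture_config()].
#' @param phenotype_terms Character vector of normalized phenotype terms to
#'   index (e.g. the gold surfaces of [gen_corpus()], normalized).
#' @return List with `phenotype_index`, `disorder_index` (both
#'   [document_index()]), `vocabulary` (a [disorder_vocabulary()]),
#'   `gold_pairs` (data frame: phenotype, disorder, a, b, c, d) and `pmids`
#'   (the full document universe; pass it to [build_transactions()] so that
#'   N equals `n_docs` and mined tables equal the gold tables).
#' @export
gen_doc_index <- function(config = fixture_config(),
                          phenotype_terms = character(0)) {
  stopifnot(config$n_docs >= 1L)
  with_seed(config$seed + 3L, {
    n_docs <- config$n_docs
    pmids <- as.character(30000000L + seq_len(n_docs))
    pheno <- unique(normalize_term(phenotype_terms))
    greek <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
               "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
               "omicron", "pi", "rho", "sigma", "tau", "upsilon")
    nd <- config$n_disorders
    stopifnot(nd <= length(greek))
    cname <- sprintf("%s syndrome", greek[seq_len(nd)])
    syns <- lapply(seq_len(nd), function(i) {
      k <- 1L + (i %% 3L)
      utils::head(c(sprintf("%s disease", greek[i]),
                    sprintf("familial %s disorder", greek[i]),
                    sprintf("%s anomaly", greek[i])), k)
    })
    vocab <- disorder_vocabulary(cname, sprintf("OMIM:%06d", 100000L + seq_len(nd)),
                                 syns)

    npl <- min(config$n_planted_pairs, length(pheno), nd)
    base_p <- config$baseline_cooccur_prob
    occ_p <- matrix(stats::runif(n_docs * length(pheno)) < base_p,
                    nrow = n_docs)
    occ_d <- matrix(stats::runif(n_docs * nd) < base_p, nrow = n_docs)
    for (j in seq_len(npl)) {
      joint <- stats::runif(n_docs) < config$planted_cooccur_prob
      occ_p[, j] <- occ_p[, j] | joint
      occ_d[, j] <- occ_d[, j] | joint
    }

    gold <- if (npl > 0L) {
      do.call(rbind, lapply(seq_len(npl), function(j) {
        p <- occ_p[, j]; d <- occ_d[, j]
        data.frame(phenotype = pheno[j], disorder = cname[j],
                   a = sum(p & d), b = sum(p & !d),
                   c = sum(!p & d), d = sum(!p & !d),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(phenotype = character(0), disorder = character(0),
                 a = integer(0), b = integer(0), c = integer(0),
                 d = integer(0), stringsAsFactors = FALSE)
    }

    pheno_index <- document_index(
      pheno, lapply(seq_along(pheno), function(j) pmids[occ_p[, j]]))
    d_terms <- character(0)
    d_lists <- list()
    for (i in seq_len(nd)) {
      names_i <- c(cname[i], vocab$synonyms[[i]])
      hits <- pmids[occ_d[, i]]
      assign_to <- sample.int(length(names_i), length(hits), replace = TRUE)
      for (k in seq_along(names_i)) {
        d_terms <- c(d_terms, names_i[k])
        d_lists[[length(d_lists) + 1L]] <- hits[assign_to == k]
      }
    }
    disorder_index <- document_index(d_terms, d_lists)
    list(phenotype_index = pheno_index, disorder_index = disorder_index,
         vocabulary = vocab, gold_pairs = gold, pmids = pmids)
  })
}

#' Write a complete fixture set to disk
#'
#' Materializes the generators as the pipeline's file formats: sentence TSV,
#' one lexicon TSV per namespace, a MEDIC-style disorder TSV, phenotype and
#' disorder index TSVs, and a gold-label JSON.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixtures <- function(config = fixture_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lex <- gen_lexicons(config)
  corp <- gen_corpus(config, lex)
  terms <- unique(normalize_term(unlist(corp$gold$surfaces)))
  idx <- gen_doc_index(config, terms)
  write_sentences(corp$sentences, file.path(out_dir, "sentences.tsv"))
  for (ns in names(lex)) {
    rows <- unlist(lapply(names(lex[[ns]]$entries), function(tm) {
      vapply(lex[[ns]]$entries[[tm]], function(id) {
        paste(tm, id, ns, sep = "\t")
      }, character(1))
    }))
    writeLines(c("term\tconcept_id\tnamespace", rows),
               file.path(out_dir, paste0(tolower(ns), ".tsv")))
  }
  med <- vapply(seq_len(nrow(idx$vocabulary)), function(i) {
    paste(idx$vocabulary$canonical_name[i],
          idx$vocabulary$omim_id[i], "",
          paste(idx$vocabulary$synonyms[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(c("DiseaseName\tDiseaseID\tAltDiseaseIDs\tSynonyms", med),
             file.path(out_dir, "medic.tsv"))
  write_document_index(idx$phenotype_index, file.path(out_dir, "idx.tsv"))
  write_document_index(idx$disorder_index, file.path(out_dir, "didx.tsv"))
  gold <- list(sentences = corp$gold, planted_pairs = idx$gold_pairs)
  jsonlite::write_json(gold, file.path(out_dir, "gold.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(out_dir)
}

#' Random annotated fixture trees
#'
#' Seeded generator of random constituency trees (at most `max_nodes` nodes)
#' over the grammatical labels the extraction patterns mention, with `SEM`
#' annotations sprinkled on adjective/noun preterminals.  Used for
#' property-style testing: bracket round-trips and exhaustive
#' matcher-versus-oracle comparisons on trees that sometimes match and
#' sometimes do not.
#'
#' @param n Number of trees.
#' @param seed Integer seed.
#' @param max_nodes Node budget per tree (SEM nodes included).
#' @return List of [ptree] objects.
#' @export
gen_fixture_trees <- function(n, seed = 42L, max_nodes = 40L) {
  phrase_labels <- c("NP", "NP", "NP", "VP", "ADJP", "PP", "S")
  pre_labels <- c("DT", "JJ", "JJ", "NN", "NN", "NNS", "NNP", "RB",
                  "CC", "VBD", "IN")
  namespaces <- c("PATO", "FMA", "MA", "CHEBI", "RXNORM", "HP", "MP",
                  "DOID", "ORDO", "OMIM", "SNOMEDCT")
  words <- c("a", "the", "large", "dilated", "esophagus", "nerve", "gait",
             "and", "or", "was", "in", "burns", "injuries", "severe",
             "abnormal", "tissue", "defect")
  with_seed(seed, {
    gen_one <- function() {
      budget <- sample(5:max_nodes, 1L)
      used <- 0L
      gen_pre <- function() {
        lab <- sample(pre_labels, 1L)
        kids <- list(ptree(sample(words, 1L)))
        used <<- used + 2L
        if (lab %in% c("JJ", "NN", "NNS", "NNP") && used + 2L <= budget &&
            stats::runif(1) < 0.55) {
          k <- sample(1:2, 1L)
          tags <- sprintf("%s:%07d", sample(namespaces, k), sample(1e6, k))
          kids <- c(kids, list(ptree("SEM", list(ptree(
            paste(sort(tags), collapse = ";"))))))
          used <<- used + 2L
        }
        ptree(lab, kids)
      }
      gen_phrase <- function(depth) {
        used <<- used + 1L
        lab <- sample(phrase_labels, 1L)
        n_kids <- sample(1:4, 1L)
        kids <- list()
        for (i in seq_len(n_kids)) {
          if (used + 3L > budget) break
          if (depth < 3L && stats::runif(1) < 0.35) {
            kids[[length(kids) + 1L]] <- gen_phrase(depth + 1L)
          } else {
            kids[[length(kids) + 1L]] <- gen_pre()
          }
        }
        if (length(kids) == 0L) {
          used <<- used + 2L
          kids <- list(ptree_leaf(sample(pre_labels, 1L), sample(words, 1L)))
        }
        ptree(lab, kids)
      }
      gen_phrase(1L)
    }
    replicate(n, gen_one(), simplify = FALSE)
  })
}
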