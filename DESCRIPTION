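Package: phenomine
Title: Phenotype Extraction from Parsed Literature and
    Phenotype-Disorder Association Mining
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts candidate phenotype terms from sentences of the
    biomedical literature by matching semantically typed phrase-structure
    parse trees against a small tree-query dialect (child, following-sister
    and coordination relations over ontology-annotated nodes), following the
    entity-quality (EQ) model in which every phenotype pairs a PATO quality
    with an anatomical, chemical or disease entity.  Candidate terms are
    normalized, filtered by document frequency against a local document
    index, and linked to Mendelian disorders by mining phenotype to
    disorder association rules from PMID co-occurrence transactions with
    the Apriori algorithm, ranked by one-sided Fisher's exact test.
    Includes seeded synthetic generators for every input (annotated parse
    trees, ontology lexicons, disorder vocabularies, document indexes) with
    gold labels, plus brute-force oracles for the tree matcher, the rule
    miner and the exact test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
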