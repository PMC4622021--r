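# phenomine

Text-mined phenotypes from parsed biomedical literature, linked to Mendelian
disorders by association rule mining.

## The problem

Curated phenotype resources (OMIM, the Human Phenotype Ontology) lag behind
the literature because phenotype descriptions — "weak extraocular muscles",
"a large dilated esophagus" — are free text with enormous surface
variability. `phenomine` implements an automated extraction pipeline for
researchers in phenomics and biomedical text mining:

1. **Sampling** — sentences are selected by eleven abnormality *trigger
   stems* (`abnormal*`, `aberra*`, `defect*`, `atypical*`, `unusual*`,
   `irregular*`, `anomal*`, `unhealthy`, `inactiv*`, `inadeq*`,
   `characteristic`), a core synonym set of the PATO quality "abnormal".
2. **Concept annotation** — tokens are matched against ontology lexicons
   (PATO, FMA, MA, ChEBI, RxNORM, HP, MP, DOID, ORDO, OMIM, ...) by greedy
   leftmost-longest dictionary lookup; hits are attached to the constituency
   parse as `SEM` nodes under each preterminal.
3. **Extraction** — nine hand-crafted tree patterns in a small Tregex-style
   dialect (child `<`, following sister `++`, coordination `+ CC`) select
   noun phrases pairing a PATO **quality** with an **entity** word — the EQ
   (entity–quality) model of phenotype composition. E.g. pattern 1:

   ```
   NP < (JJ < (SEM < /PATO/) ++ (/NN.?/ < (SEM < /FMA|RXNORM|CHEBI|MA/)))
   ```

4. **Filtering** — candidates are normalized, deduplicated, and kept when
   their document frequency (df) against a PMID index is ≥ 10.
5. **Association mining** — per-PMID transactions of `p/phenotype` and
   `d/disorder` items (disorder synonyms unified via a MEDIC-style
   vocabulary) are mined with Apriori (sup = 2.5e-7, conf = 0.1,
   minlen = maxlen = 2), post-filtered to {phenotype} → {disorder} rules,
   and ranked by one-sided Fisher's exact test on each rule's 2×2 table:
   p = P(X ≥ a) with X hypergeometric on the fixed margins.

Every statistical component ships with an independent brute-force oracle
(`brute_force_match`, `brute_force_rules`, `fisher_p_oracle`) and seeded
synthetic generators (`gen_lexicons`, `gen_corpus`, `gen_doc_index`)
produce all inputs with gold labels, so the pipeline is fully testable
offline.

## Worked example

```r
library(phenomine)

lex  <- gen_lexicons()
tree <- read_ptb("(NP (DT a) (JJ large) (JJ dilated) (NN esophagus))")
ann  <- assemble_semantic_tree(tree, annotate(tree_yield(tree), lex))
write_ptb(ann)
#> [1] "(NP (DT a) (JJ large (SEM PATO:0000012)) (JJ dilated (SEM PATO:0000013)) (NN esophagus (SEM FMA:0000001)))"

length(match_pattern(builtin_patterns()$p1, ann))
#> [1] 2
```

Two matches — one per PATO adjective — rooted at the same NP, which
downstream extraction collapses into one candidate with surface
`"a large dilated esophagus"`, qualities `{PATO:large, PATO:dilated}` and
entity `{FMA:esophagus}`.

End-to-end on synthetic data:

```r
cfg   <- fixture_config(seed = 7)
corp  <- gen_corpus(cfg)
cands <- extract_candidates(corp$sentences)
idx   <- gen_doc_index(cfg, cands$normalized)
db    <- build_transactions(idx$phenotype_index, idx$vocabulary,
                            idx$disorder_index, universe = idx$pmids)
print(head(as.data.frame(rank_rules(apriori(db))), 3), digits = 4)
#>                        antecedent       consequent   a b  c    d support_count
#> 82 p/unusual median hydrocephalus d/gamma syndrome 110 7 11 4872           110
#> 52       p/irregular clinodactyly d/delta syndrome 104 8 12 4876           104
#> 9      p/inadequate hydrocephalus d/alpha syndrome 102 8 10 4880           102
#>    support confidence    p_value
#> 82  0.0220     0.9402 4.301e-203
#> 52  0.0208     0.9286 1.970e-191
#> 9   0.0204     0.9273 3.138e-190
```

The top-ranked rules are exactly the planted phenotype–disorder pairs, with
contingency tables equal to the generator's bookkeeping (`idx$gold_pairs`).

A command-line launcher covering the pipeline stages
(`pm select | annotate | match | extract | mine | fixtures`) is installed at
`system.file("cli", "pm", package = "phenomine")`.

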