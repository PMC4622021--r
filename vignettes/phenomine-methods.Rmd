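---
title: "Methods: semantically typed tree matching and phenotype–disorder rule mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantically typed tree matching and phenotype–disorder rule mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomine)
```

## The model

`phenomine` treats a phenotype mention as an **EQ pair**: a *quality* drawn
from PATO (the kind of abnormality — enlarged, irregular, absent) composed
with an *entity* (what is abnormal — an anatomical structure, chemical,
process phenotype or disease term). A mention is only accepted when the two
halves stand in a specific syntactic configuration inside a noun phrase of a
constituency parse, which is what separates "a large dilated esophagus"
(phenotype) from "a large study of the esophagus" (not one).

The pipeline is: trigger-stem sentence sampling → dictionary concept
annotation → semantic tree assembly → tree-pattern extraction → document
frequency filtering → transaction building → Apriori rule mining → Fisher
ranking → database export. Parsing itself is out of scope: the package
consumes Penn-Treebank bracket strings produced by any constituency parser,
and its claims are deliberately independent of parser quality.

## Trigger sampling

Eleven lowercase prefix stems (see `trigger_stems()`) select sentences likely
to describe abnormal phenotypes. Matching is token-prefix and
case-insensitive after stripping surrounding punctuation; the stems are
wildcards, so `inactiv` matches "inactivation". This is a recall-oriented
filter: it bounds the corpus handed to the expensive stages and anchors the
extracted phenotypes in abnormality contexts, at the cost of missing
sentences that describe deviation without one of the stems.

## Concept annotation

A single pluggable dictionary matcher stands in for web-service annotators
and statistical taggers: per namespace, greedy leftmost-longest,
case-insensitive matching over the token sequence. Namespaces are matched
independently (a token may be a PATO hit and an HP hit simultaneously), but
within one namespace a token belongs to at most one span — the behaviour of
the exhaustive leftmost-longest oracle the tests compare against. No word
sense disambiguation is attempted; all senses of a term are retained.

Annotations are serialized into the parse as a `SEM` node appended to each
covered preterminal, holding the `;`-joined, sorted `NAMESPACE:ID` set.
Multi-token concept spans project onto *every* covered preterminal, because
the extraction patterns test individual `JJ`/`NN.?` nodes. Stripping `SEM`
nodes recovers the original tree exactly, which keeps annotation reversible
and testable.

## The pattern dialect

The nine built-in patterns use three operators:

* `A < B` — immediate dominance;
* `A ++ B` — *any* later sister, not necessarily adjacent. This reading is
  forced by the canonical example "a large dilated esophagus", where the
  first adjective must see a non-adjacent noun;
* `A + CC B` — coordination: A and B are sisters with a `CC`-labeled sister
  strictly between them, the reading forced by examples such as "abnormal
  dentition and delayed tooth eruption".

Plain node tests are exact label equality; `/…/` tests are unanchored
regular expressions, so `/NN.?/` matches all noun tags but never `NP`, and
`/PATO/` matches anywhere in a serialized concept set. Relation clauses
chain on their head node, and parenthesized groups flatten onto the grouped
head — in pattern 1 both the `SEM` child test and the `++` sister test
constrain the same `JJ`.

`match_pattern()` returns one result per distinct binding of pattern nodes
to tree nodes, ordered by matched-root preorder position then lexicographic
binding order. Its verification oracle `brute_force_match()` enumerates
every assignment of pattern nodes to label-compatible tree nodes and filters
by independent relation predicates; the two are compared exhaustively
(equality of binding sets) in the acceptance suite. Downstream extraction
deduplicates on the matched root, so several bindings at one NP yield a
single candidate.

## Extraction and document-frequency filtering

The candidate surface form is the full word yield of the matched NP,
determiners included; `normalize_term()` (lowercase, leading determiners
stripped repeatedly, whitespace collapsed) is used only for deduplication
and index lookup. Accessions `PM1, PM2, …` are assigned in first-occurrence
order and are deterministic for a given corpus; no claim is made that they
reproduce any previously published numbering.

Document frequency is computed against a local `document_index()` (term →
PMID list, capped at 10,000 per term, mirroring a `retmax`-limited
E-utilities query). The df ≥ 10 filter is inclusive. A live-query adapter is
deliberately out of scope; any index source can be materialized to the TSV
format.

## Transactions, Apriori and Fisher ranking

Each PMID becomes a transaction of `p/term` and `d/canonical-name` items.
Disorder synonym lists (from a MEDIC-style vocabulary filtered to entries
with OMIM identifiers) are unified under the canonical name, so synonym
query expansion increases evidence without fragmenting items; a synonym
shared by two canonical disorders is an error unless explicitly allowed.
Single-item transactions are retained because support fractions are defined
over all N transactions — this is what makes sup = 2.5e-7 translate to a
two-document restriction at N ≈ 7 million (`min_support_count()`).

One open point is what N counts: per-term retrieval can only observe PMIDs
returned by at least one query, but the synthetic world knows its full
document universe. `build_transactions(universe =)` accepts the universe
explicitly; the generated-data tests pass it so that mined 2×2 tables equal
the generator's gold tables exactly. Without it, N counts retrieved PMIDs —
the honest default for live-like data.

Mining is level-wise Apriori with support-based candidate pruning
(general up to any `maxlen`, oracle-tested to 3, although the defaults
minlen = maxlen = 2 reduce it to pair counting), rule generation with
single-item consequents, a confidence threshold, and a type post-filter
keeping only {phenotype} → {disorder} rules. Each rule carries
a = both, b = phenotype only, c = disorder only, d = neither (a+b+c+d = N),
and is ranked by the one-sided Fisher's exact p-value
`P(X ≥ a)` for hypergeometric X with the margins fixed. One-sided is a
design choice the source description leaves implicit: ranking *enrichment*
requires the over-representation tail (this also matches the reference
arules implementation). Raw p-values are reported; a Benjamini–Hochberg
column is available via `adjust_rules()` but clearly labeled as an extra.
Ties rank by descending support count, then antecedent.

Numerically, `fisher_p()` is `phyper(a − 1, …, lower.tail = FALSE)`; its
oracle sums hypergeometric terms from `lchoose` and agrees within 1e-12 on
tables up to total 30, and with `fisher.test(alternative = "greater")`.

## The synthetic world

The generators are first-class, tested code, and their defaults are fixed
once:

* **Corpus** (`gen_corpus`): templates instantiate each of the nine patterns
  (72% of sentences, 8% each) and five distractor families (28%) modeled on
  realistic failure classes — quality with no entity word, entity with no
  quality, inverted word order, comma coordination without a conjunction,
  and unremarkable no-trigger sentences. Trigger coverage of positives is
  guaranteed by drawing the quality adjective (or adverb) from
  trigger-bearing PATO synonyms of "abnormal". Surface text is synthetic
  template English, not natural prose.
* **Lexicons** (`gen_lexicons`): PATO plus nine entity namespaces with
  disjoint vocabularies (so no cross-namespace accidents), always including
  the worked-example terms.
* **Document indexes** (`gen_doc_index`): 5,000 documents; every term occurs
  independently per document with probability 0.002 (expected df ≈ 10, the
  filter boundary); 5 planted phenotype–disorder pairs get an additional
  joint occurrence with probability 0.02 — ten times baseline, ≈ 100
  co-occurring documents. Independent Bernoulli occurrence with a boosted
  joint is the simplest model under which Fisher's exact test is calibrated.
  40 phenotype terms and 12 disorders (2–4 synonym strings each, hits
  partitioned across synonyms to exercise unification) are a scale where
  both planted and chance co-occurrences appear. Gold 2×2 tables are counted
  from the realized incidence, so they are exact by construction.

What a green test establishes: the matcher equals its oracle, extraction is
faithful to the stated templates, mining statistics are exact, and planted
signal is recovered and ranked first. What it does not establish: recall on
natural prose, parser robustness, lexicon coverage, or the behaviour of the
published-scale corpus — those headline counts (13,636 candidates, 28,155
hypotheses, …) require external corpora and services and are explicitly not
reproduced; only their internal arithmetic (stratification percentages and
the support conversion) is recomputed.

## Degenerate inputs and edge behaviour

Empty sentence sets select to empty; an empty transaction database refuses
to mine; an all-zero df list stratifies to zeros; `min_support_count` floors
at one document and guards float rounding of `ceiling(sup × N)`;
`brute_force_match` refuses trees over 40 nodes and assignment spaces over
5e6; PM accessions restart at PM1 per extraction run. Bracket parse errors
and pattern syntax errors always carry character positions.

## Known limitations

Acronym expansion, word-sense disambiguation, conjunctive-term decomposition
and HP-alignment of extracted terms are out of scope. The OBO loader covers
the minimal `[Term]`/name/EXACT-synonym subset. The dialect implements only
the three operators the nine patterns use — no `<<`, `..`, negation or
back-references.
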