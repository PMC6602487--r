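# phenotext

Dictionary-based recognition of Human Phenotype Ontology (HPO) concepts in
clinical free text, for R.

Deep phenotyping pipelines — gene prioritization for suspected Mendelian
disease, cohort curation from electronic health records, corpus annotation
for clinical NLP — all start from the same step: finding the phenotype
mentions in a narrative and mapping each one to a standardized HPO concept
(`HP:NNNNNNN`). Doing this by hand is slow and inconsistent; phenotext
provides the automated backend for it:

- **Ontology → lexicon.** `parse_obo()` reads an OBO file (the real
  `hp.obo` or the bundled miniature fixture); `build_lexicon()` collects
  the names and synonyms of every non-obsolete term under a subtree root —
  for real HPO, *phenotypic abnormality* (`HP:0000118`).
- **Matching.** `build_automaton()` compiles the lexicon into an
  Aho–Corasick keyword automaton over whole tokens; `find_matches()`
  reports every lexicon phrase that equals a contiguous run of document
  tokens, with a *longest match only* policy by default and an
  *allow partial match* option that also reports nested mentions
  ("stature" inside "short stature").
- **Negation.** `apply_negex()` implements NegEx-style detection: trigger
  phrases (pre-negation, post-negation, pseudo-negation, termination) flag
  annotations within a bounded token window inside each sentence, so "denies
  fever" yields a *negated* fever annotation. The ~40-phrase trigger lexicon
  is a plain-text, user-replaceable file.
- **Engines and ensembles.** External annotators that emit UMLS CUIs plug in
  via `map_cui_to_hpo()` (CUI → HPO through ontology cross-references) or as
  replay adapters; `ensemble_union()` merges engines by set union —
  trading false positives for a lower false-negative rate — and
  `run_pipeline()` drives the whole thing.
- **Formats.** Stand-off JSON (character-offset annotations separate from
  the text), an RFC 4180 CSV table, and a Phenolyzer-compatible phenotype
  list (`export_phenolyzer()`), ready to paste into gene-prioritization
  tools.
- **Evaluation.** Precision, recall and F1 over distinct
  (document, HPO concept) pairs — `to_pairs()`, `evaluate_pairs()`,
  `aggregate_metrics()` (micro/macro) — with degenerate cases defined so
  aggregation is always total:
  precision = tp/(tp+fp), recall = tp/(tp+fn), F1 = 2PR/(P+R).
- **Fixtures.** `write_mini_ontology()` and `generate_note()` build a
  12-term ontology and synthetic notes with planted, ground-truthed
  mentions, so every stage is testable offline.

## Worked example

```r
library(phenotext)

onto <- parse_obo(system.file("extdata", "mini_hp.obo", package = "phenotext"))
lex  <- build_lexicon(onto, mini_root_id())
m    <- build_automaton(lex)

text <- "Patient has short stature and denies fever today."
ann  <- apply_negex(text, find_matches(m, text))
ann
#>   start end       surface     hpo_id      hpo_name negated engine
#> 1    12  25 short stature HP:5000002 Short stature   FALSE   dict
#> 2    37  42         fever HP:5000007         Fever    TRUE   dict
```

Two mentions were found: "short stature" at characters 12–25 (0-based,
half-open) normalized to `HP:5000002`, asserted; and "fever" normalized to
`HP:5000007`, flagged negated because it sits inside the 5-token scope of the
pre-negation trigger "denies". A Phenolyzer list keeps only the asserted
concepts:

```r
export_phenolyzer(annotated_document("note1", text, ann))
#> [1] "short stature"
```

Scoring predictions against a gold standard works on distinct
document–concept pairs:

```r
evaluate_pairs(data.frame(doc_id = "n1", hpo_id = c("HP:1", "HP:2", "HP:4")),
               data.frame(doc_id = "n1", hpo_id = c("HP:1", "HP:2", "HP:3")))
#> tp=2 fp=1 fn=1 precision=0.667 recall=0.667 f1=0.667
```

## Command line

A thin Rscript wrapper exposes the library:

```sh
Rscript inst/cli/phenotext.R fixtures --out fx --n 2 --seed 3
Rscript inst/cli/phenotext.R parse --obo fx/mini_hp.obo --root HP:5000001 \
    --format standoff --out out fx/note_001.txt
Rscript inst/cli/phenotext.R eval fx/note_001.gold.json out/note_001.json
#> tp,fp,fn,precision,recall,f1
#> 1,0,0,1,1,1
```

Flags mirror the library options: `--engine dict[,replay:PATH]`,
`--no-longest-only`, `--allow-partial`, `--no-negex`, `--triggers PATH`,
`--format standoff|phenolyzer|csv`, `--include-negated`.

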