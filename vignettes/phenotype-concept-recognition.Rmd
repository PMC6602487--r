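---
title: "Methods: dictionary-based HPO concept recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-based HPO concept recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotext)
```

## The problem

Phenotype *concept recognition* is stricter than named-entity recognition:
a system must both locate a span of clinical text and normalize it to a
standardized concept — here a Human Phenotype Ontology (HPO) term. The
recognized concepts feed gene-prioritization tools (Phenolyzer and
relatives), cohort databases, and annotated training corpora. phenotext
implements the automated half of a human-in-the-loop curation workflow:
fast, deterministic, dictionary-based extraction with negation detection,
plus the interchange formats and the evaluation harness around it.

## The lexicon

Matching is dictionary-based. From a parsed OBO ontology, the lexicon takes
**every non-obsolete term under a configured subtree root** — for the real
HPO that root is *phenotypic abnormality* (`HP:0000118`), the subtree whose
descendants are the clinically meaningful phenotypes — and creates one entry
per term name and one per synonym.

Choices made here, and why:

- **All four synonym scopes (EXACT, BROAD, NARROW, RELATED) are included by
  default.** Which scopes a dictionary should use is genuinely open; broader
  scopes raise recall at some cost to precision, and a human reviewer
  downstream can discard loose hits. `include_scopes` makes the choice
  explicit and reversible.
- **Obsolete terms stay in the ontology object but never enter the
  lexicon.** Matching retired labels would create annotations that cannot be
  mapped forward; keeping the terms themselves preserves xref lookups.
- **Ambiguous strings are kept ambiguous.** Distinct concepts sharing a
  normalized label (true in the real HPO) each keep their entry; the matcher
  reports same-span ties sorted by concept id rather than guessing.

Normalization is deliberately minimal: case folding (off via
`normalizer_config(case_sensitive = TRUE)`), punctuation to separators,
whitespace collapsed. It is idempotent, and the same function normalizes
both the lexicon and the document, which is what makes token-run equality a
sound matching criterion.

## The matcher

The automaton is a classic Aho–Corasick keyword machine — goto trie,
failure links, merged output sets — built once per lexicon in time linear in
total pattern length, and run once per document. Two properties matter:

- **The alphabet is whole tokens, not characters.** A pattern can only match
  a contiguous run of document tokens, so "he" can never fire inside
  "ushers" and clinical terms stay word-aligned. Sub-word hits would flood
  false positives at no recall benefit.
- **Policies are span filters, not search changes.** The automaton always
  finds the complete match set; *longest match only* (default) then
  suppresses any match strictly contained in another match's character
  span, and *allow partial match* reports the nested ones too. The two
  options are exact duals, which is what the duality property test checks:
  partial output = longest output ∪ nested matches.

Matches may cross sentence boundaries: a token run is a token run. Clinical
phrases essentially never span a sentence terminator, and tying matching to
the sentence splitter would couple two modules needlessly. Negation, by
contrast, is sentence-bounded by construction (below).

Offsets everywhere are 0-based and half-open, so `substr(text, start + 1,
end)` recovers the surface and spans concatenate without off-by-ones; the
stand-off JSON uses the same convention.

## Negation

`apply_negex()` follows the NegEx recipe: within each sentence, find trigger
phrases, then flag annotations in their scope.

- **Categories.** `PRE_NEG` ("no", "denies", "absence of") negates forward;
  `POST_NEG` ("was ruled out", "unlikely") negates backward; `PSEUDO_NEG`
  ("no increase", "not ruled out") is a phrase that merely *looks* negating
  and masks any overlapping real trigger; `TERMINATION` ("but", "however")
  ends a scope early.
- **Window.** Default scope is 5 tokens, the classic NegEx window — an
  annotation is negated if its first token starts within 5 tokens after a
  pre-negation trigger (mirrored for post-negation) with no termination
  trigger in between. The window is per-rule in the trigger file; an empty
  value means "to the sentence boundary". Scope is monotone: shrinking the
  window can only turn negated flags off, never on.
- **Tie-breaking.** At one start position the longest trigger wins, which is
  what lets "no increase" (pseudo) defeat "no" (pre-negation) without
  special cases.

The ~40-phrase starter trigger file is a plain-text, tab-separated,
user-replaceable config; it is a starting point, not a claim of coverage.
POST_NEG rules are included because they cost nothing and are removable by
editing the file. Negation is a post-processing stage applied to
annotations from *any* engine, not a matcher feature — external annotators'
output gets the same treatment as the dictionary's.

Sentence splitting is intentionally crude (split at `. ! ? ;` and newline,
terminator attached left, blank segments dropped). Clinical notes are not
well-formed prose; a heavier splitter would add failure modes without
changing the negation semantics being tested.

## Engines and the ensemble

External annotators enter through a small contract: anything with an `id`
and a `run(text)` returning annotations. Annotators that emit UMLS CUIs are
adapted by `map_cui_to_hpo()`: a CUI maps to **every** HPO term listing it
as a cross-reference — a one-to-many mapping the shared-xref fixture case
exercises — and unmapped CUIs are dropped with a count. Live services are
represented by replay adapters (recorded stand-off files); the pipeline
treats an engine failure as an empty result plus a warning, never a crash.

`ensemble_union()` deduplicates on `(start, end, hpo_id)` — surface is
derivable from the span, and the engine label is deliberately excluded so
the same finding from two engines is one finding. When duplicates disagree
on negation, the merged annotation is negated **only if all copies are
negated**: the union exists to maximize recall of asserted phenotypes, so
assertion wins conflicts. This is an interpretation (the merge rule for
negation disagreement is not otherwise constrained), recorded here.

## Evaluation

The scoring unit is the distinct **(document, HPO id) pair**: span offsets
and repeated mentions do not affect the score, and negated annotations are
excluded unless requested. Degenerate conventions keep aggregation total:
empty-vs-empty scores 1.0 everywhere; empty predictions against non-empty
gold score 0.0 rather than NaN. Both micro (pool counts, default) and macro
(average rates) aggregation are provided; macro reproduces per-annotator
averaging. Only exact-id matching is implemented — granting credit for
ancestors or descendants of a gold concept is a different evaluation design
and is left out deliberately.

## The synthetic generator, and what passing proves

`generate_note()` plants `n_mentions` lexicon surfaces (synonyms with
probability `synonym_rate`) into one-mention carrier sentences; with
probability `negation_rate` the sentence carries a pre-negation trigger
directly before the mention, inside the default 5-token window. The carrier
vocabulary is a closed 24-word list **checked against the lexicon's tokens
at generation time** (a collision is an error), and mentions never share a
sentence. Consequently the dictionary engine plus negation must recover
exactly the planted (concept, negated) set — recall and precision are
provably 1.0, not probabilistically so — and the end-to-end check runs this
over the full recipe grid `synonym_rate × negation_rate ∈ {0, 0.5, 1}²`
with 10 seeded notes per cell and 1–20 mentions per note.

What this does **not** show: performance on real clinical text. Real notes
contain spelling variants ("renal hypertension" vs "renovascular
hypertension"), abbreviations, hyponymy, hedging, family-history
attribution, and gold standards built by adjudication. Dictionary matching
is known to lose recall on all of these; the synthetic grid verifies the
machinery (offsets, policies, negation scopes, formats) end to end, nothing
more. Fuzzy matching, stemming, and uncertainty detection are out of scope
by design.

The bundled 12-term ontology fixture is built to exercise the structural
edge cases in miniature: a diamond (multi-parent) term, two obsolete terms,
synonyms in all four scopes, two terms sharing one UMLS xref, a nested
name/synonym pair ("Short stature" / "Stature"), and one term outside the
build subtree that must never match.

## Numerical and degenerate-input choices

- Problem sizes in the verification suite: 500 random lexicon/text cases
  against a naive scan oracle, 200 ensemble cases, 40 stand-off
  round-trips, 90 grid notes. The full suite runs in under half a minute.
- Empty text, empty lexicons, empty rule lists, zero-annotation documents
  and zero-length pair sets all have defined, tested behavior (empty output
  or an informative error, never silence).
- Determinism: parsing, matching and generation have no hidden state; the
  generator seeds a private RNG stream and restores the caller's.

## Limitations

Dictionary matching only (no statistical NER), exact-id evaluation only,
English-centric trigger defaults, a sentence splitter that trusts
terminator characters, and no handling of hypothetical or family-history
mentions — those were handled by human review in the workflow this backend
supports, and an interactive review layer is the intended complement to
this package.
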