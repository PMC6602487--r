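Package: phenotext
Title: Dictionary-Based Recognition of Human Phenotype Ontology Concepts in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes Human Phenotype Ontology (HPO) concepts in clinical
    free text. Parses OBO ontology files, builds a matching lexicon from term
    names and synonyms under the phenotypic-abnormality subtree, locates
    mentions with an Aho-Corasick keyword automaton operating on token runs,
    flags negated mentions with a NegEx-style trigger-rule engine, maps
    UMLS CUI annotations from external annotators onto HPO via ontology
    cross-references, and combines engines by set union. Annotations are
    exchanged as stand-off JSON keyed by character offsets, exported as CSV
    tables or Phenolyzer-compatible phenotype lists, and scored against gold
    standards as precision, recall and F1 over distinct document-concept
    pairs. Includes a synthetic note generator with planted ground truth and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
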