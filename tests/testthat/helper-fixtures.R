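# Shared fixture objects, built once per test run.

mini_obo_path <- system.file("extdata", "mini_hp.obo", package = "phenotext")
mini_onto <- parse_obo(mini_obo_path)
mini_lex <- build_lexicon(mini_onto, mini_root_id())
mini_matcher <- build_automaton(mini_lex)

# A lexicon object built directly from token strings (bypassing an ontology),
# for matcher-only tests.
make_lexicon <- function(tokens, hpo_id,
                         hpo_name = paste("Term", hpo_id),
                         config = normalizer_config()) {
  n <- length(tokens)
  structure(
    data.frame(tokens = tokens, hpo_id = hpo_id,
               hpo_name = rep_len(hpo_name, n),
               source = rep_len("NAME", n),
               source_scope = rep_len(NA_character_, n),
               original_text = tokens, stringsAsFactors = FALSE),
    root_id = "HP:0000000", config = config,
    class = c("hpo_lexicon", "data.frame"))
}

negex_regression_cases <- function() {
  path <- system.file("extdata", "negex_regression.tsv",
                      package = "phenotext")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(text = vapply(parts, `[[`, character(1), 1L),
             target = vapply(parts, `[[`, character(1), 2L),
             expected = vapply(parts, `[[`, character(1), 3L) == "1",
             stringsAsFactors = FALSE)
}

make_annotations <- function(text, surfaces, hpo_id, negated = FALSE,
                             engine = "dict") {
  rows <- lapply(seq_along(surfaces), function(i) {
    at <- regexpr(surfaces[i], text, fixed = TRUE)[1]
    stopifnot(at > 0)
    data.frame(start = at - 1L, end = at - 1L + nchar(surfaces[i]),
               surface = surfaces[i], hpo_id = hpo_id[i],
               hpo_name = hpo_id[i], negated = FALSE, engine = engine,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann$negated <- rep_len(negated, nrow(ann))
  ann
}
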