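# Synthetic fixtures: a miniature ontology and notes with planted mentions.

mini_obo_lines <- function() c(
  "format-version: 1.2",
  "ontology: mini-hp-fixture",
  "",
  "[Term]",
  "id: HP:5000001",
  "name: Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000002",
  "name: Short stature",
  "synonym: \"Decreased body height\" EXACT []",
  "xref: UMLS:C0349588",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000003",
  "name: Abnormal stature",
  "synonym: \"Stature\" RELATED []",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000004",
  "name: Abnormality of the kidney",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000005",
  "name: Abnormality of the vasculature",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000006",
  "name: Renal hypertension",
  "xref: UMLS:C1306620",
  "is_a: HP:5000004 ! Abnormality of the kidney",
  "is_a: HP:5000005 ! Abnormality of the vasculature",
  "",
  "[Term]",
  "id: HP:5000007",
  "name: Fever",
  "synonym: \"Febrile episode\" BROAD []",
  "xref: UMLS:C0015967",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000008",
  "name: Hyperthermia",
  "xref: UMLS:C0015967",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000009",
  "name: Cough",
  "synonym: \"Tussis\" EXACT []",
  "synonym: \"Chronic cough\" NARROW []",
  "is_a: HP:5000001 ! Phenotypic abnormality (fixture root)",
  "",
  "[Term]",
  "id: HP:5000010",
  "name: Dyspnea",
  "is_obsolete: true",
  "",
  "[Term]",
  "id: HP:5000011",
  "name: Seizure",
  "is_obsolete: true",
  "",
  "[Term]",
  "id: HP:5000012",
  "name: Mode of inheritance (fixture)",
  ""
)

#' Id of the miniature fixture's subtree root
#' @return The CURIE of the fixture term playing the role of the
#'   phenotypic-abnormality root (HP:0000118 in the real HPO).
#' @export
mini_root_id <- function() "HP:5000001"

#' Write the miniature ontology fixture
#'
#' Writes a fixed 12-term OBO file in the real hp.obo dialect, small enough
#' to verify by eye yet exercising every structural case the pipeline must
#' handle: a subtree root standing in for phenotypic abnormality, a
#' multi-parent (diamond) term, two obsolete terms, synonyms in all four
#' scopes, two terms sharing a UMLS cross-reference, a nested name/synonym
#' pair ("Short stature" / "Stature"), and one term outside the subtree that
#' must never enter the lexicon. Identical content ships as
#' `inst/extdata/mini_hp.obo`.
#'
#' @param path Output path.
#' @export
write_mini_ontology <- function(path) {
  writeLines(mini_obo_lines(), path, useBytes = TRUE)
  invisible(NULL)
}

# Carrier vocabulary for synthetic notes; checked at generation time to be
# disjoint from the lexicon's tokens so no template word can ever produce an
# accidental dictionary hit, making perfect recovery provable.
carrier_words <- function() {
  c("patient", "presents", "with", "at", "clinic", "today", "exam", "shows",
    "again", "history", "includes", "per", "family", "reports", "since",
    "last", "week", "denies", "no", "visit", "negative", "for", "without",
    "seen")
}

assert_templates <- function() c(
  "Patient presents with %s at clinic today.",
  "Exam shows %s again.",
  "History includes %s per family.",
  "Patient reports %s since last week."
)

negated_templates <- function() c(
  "Patient denies %s at clinic today.",
  "Exam shows no %s today.",
  "Visit negative for %s again.",
  "Patient without %s since last week."
)

#' Generate a synthetic clinical note with known ground truth
#'
#' Samples lexicon entries (a synonym with probability `synonym_rate` when
#' any synonym entry exists, otherwise a term name) and embeds each into a
#' one-mention carrier sentence; with probability `negation_rate` the
#' sentence carries a pre-negation trigger directly before the mention,
#' inside the default 5-token NegEx window. Carrier words are verified to be
#' disjoint from the lexicon's tokens, so running the dictionary engine plus
#' negation on the note recovers exactly the planted annotations. Output is
#' byte-identical for equal seeds; the caller's RNG state is untouched.
#'
#' @param lexicon A non-empty `hpo_lexicon`.
#' @param n_mentions Number of planted mentions (>= 0).
#' @param negation_rate,synonym_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed controlling all sampling.
#' @param doc_id Document id; defaults to `"synthetic_<seed>"`.
#' @return An [annotated_document()] whose annotations are the ground truth
#'   (engine `"gold"`).
#' @export
generate_note <- function(lexicon, n_mentions, negation_rate = 0,
                          synonym_rate = 0, seed = 1L,
                          doc_id = sprintf("synthetic_%d", seed)) {
  stopifnot(inherits(lexicon, "hpo_lexicon"),
            n_mentions >= 0,
            negation_rate >= 0, negation_rate <= 1,
            synonym_rate >= 0, synonym_rate <= 1)
  if (n_mentions > 0 && nrow(lexicon) == 0L) {
    stop("cannot plant mentions from an empty lexicon", call. = FALSE)
  }
  lex_tokens <- unique(unlist(strsplit(lexicon$tokens, " ", fixed = TRUE)))
  clash <- intersect(carrier_words(), lex_tokens)
  if (length(clash)) {
    stop(sprintf("carrier vocabulary collides with lexicon token(s): %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  names_pool <- which(lexicon$source == "NAME")
  syn_pool <- which(lexicon$source == "SYNONYM")

  sentences <- character(0)
  ann <- empty_annotations()
  offset <- 0L
  if (n_mentions == 0L) {
    sentences <- "Patient seen at clinic today."
  } else {
    for (i in seq_len(n_mentions)) {
      use_syn <- length(syn_pool) > 0L && stats::runif(1) < synonym_rate
      pool <- if (use_syn) syn_pool else names_pool
      e <- pool[[sample.int(length(pool), 1L)]]
      negated <- stats::runif(1) < negation_rate
      tmpl_pool <- if (negated) negated_templates() else assert_templates()
      tmpl <- tmpl_pool[[sample.int(length(tmpl_pool), 1L)]]
      surface <- lexicon$original_text[e]
      sent <- sprintf(tmpl, surface)
      mention_at <- regexpr("%s", tmpl, fixed = TRUE)[1] - 1L  # 0-based
      start <- offset + mention_at
      ann <- rbind(ann, data.frame(
        start = start, end = start + nchar(surface), surface = surface,
        hpo_id = lexicon$hpo_id[e], hpo_name = lexicon$hpo_name[e],
        negated = negated, engine = "gold", stringsAsFactors = FALSE))
      sentences <- c(sentences, sent)
      offset <- offset + nchar(sent) + 1L   # sentences joined by one space
    }
  }
  annotated_document(doc_id, paste(sentences, collapse = " "), ann)
}
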