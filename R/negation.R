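# NegEx-style negation detection over stand-off annotations.

#' Split text into sentence spans
#'
#' Sentences end at `.`, `!`, `?`, `;` or a newline, with the terminator
#' attached to the preceding sentence. Leading/trailing whitespace is
#' excluded from each span and whitespace-only segments are dropped, so the
#' spans cover exactly the non-blank text without overlapping.
#'
#' @param text Document string.
#' @return Data frame with 0-based half-open columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  term <- which(chars %in% c(".", "!", "?", ";", "\n"))
  cut_end <- unique(c(term, length(chars)))   # 1-based inclusive segment ends
  seg_start <- c(1L, head(cut_end, -1L) + 1L)
  keep <- seg_start <= cut_end
  seg_start <- seg_start[keep]; seg_end <- cut_end[keep]
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(seg_start)) {
    s <- seg_start[i]; e <- seg_end[i]
    while (s <= e && grepl("^\\s$", chars[s])) s <- s + 1L
    while (e >= s && grepl("^\\s$", chars[e])) e <- e - 1L
    if (s > e) next
    starts <- c(starts, s - 1L)  # to 0-based
    ends <- c(ends, e)
  }
  data.frame(start = starts, end = ends)
}

#' Negation trigger rules
#'
#' Reads a tab-separated trigger lexicon: one rule per line,
#' `phrase<TAB>category<TAB>max_scope`. Categories are `PRE_NEG` (negates
#' following annotations), `POST_NEG` (negates preceding annotations),
#' `PSEUDO_NEG` (looks like a negation but is not; masks overlapping
#' triggers) and `TERMINATION` (conjunctions that end a negation scope).
#' `max_scope` is a token count; empty means "to the sentence boundary" and
#' is meaningless for `PSEUDO_NEG`/`TERMINATION`. Lines starting with `#`
#' are comments.
#'
#' @param path Path to a rule file. The default is the bundled starter set
#'   of ~40 English clinical triggers.
#' @return Data frame of class `negex_rules` with columns `phrase`,
#'   `category`, `max_scope`.
#' @export
read_trigger_rules <- function(path = system.file("extdata",
                                                  "negex_triggers.tsv",
                                                  package = "phenotext")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rules <- data.frame(
    phrase = vapply(parts, `[[`, character(1), 1L),
    category = vapply(parts, `[[`, character(1), 2L),
    max_scope = vapply(parts, function(p) {
      if (length(p) >= 3 && nzchar(trimws(p[3]))) as.integer(p[3])
      else NA_integer_
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  bad <- !rules$category %in% c("PRE_NEG", "POST_NEG", "PSEUDO_NEG",
                                "TERMINATION")
  if (any(bad)) {
    stop(sprintf("unknown trigger category '%s'", rules$category[bad][1L]),
         call. = FALSE)
  }
  structure(rules, class = c("negex_rules", "data.frame"))
}

#' Helper to build a rule table in code
#'
#' @param phrase,category,max_scope Vectors recycled to equal length.
#' @return A `negex_rules` data frame.
#' @export
negex_rules <- function(phrase, category, max_scope = NA_integer_) {
  structure(data.frame(phrase = phrase,
                       category = rep_len(category, length(phrase)),
                       max_scope = rep_len(as.integer(max_scope),
                                           length(phrase)),
                       stringsAsFactors = FALSE),
            class = c("negex_rules", "data.frame"))
}

#' Apply NegEx-style negation to annotations
#'
#' Within each sentence, trigger phrases are located on the normalized token
#' sequence (at a given start position the longest trigger wins, and a
#' `PSEUDO_NEG` occurrence masks any overlapping `PRE_NEG`/`POST_NEG`
#' occurrence). A `PRE_NEG` trigger negates annotations beginning within
#' `max_scope` tokens after it (to the sentence end when `max_scope` is
#' `NA`), unless a `TERMINATION` trigger intervenes. `POST_NEG` applies the
#' mirrored rule to annotations ending before the trigger. Spans, concepts
#' and row order are untouched; only `negated` changes.
#'
#' @param text Document string the annotations index into.
#' @param annotations Annotation data frame (any engine).
#' @param rules A `negex_rules` table, e.g. [read_trigger_rules()].
#' @param sentences Optional precomputed [split_sentences()] output.
#' @return The annotation data frame with the `negated` flag set.
#' @examples
#' ann <- data.frame(start = 7L, end = 12L, surface = "fever",
#'                   hpo_id = "HP:5000007", hpo_name = "Fever",
#'                   negated = FALSE, engine = "dict")
#' apply_negex("denies fever", ann)$negated   # TRUE
#' @export
apply_negex <- function(text, annotations, rules = read_trigger_rules(),
                        sentences = split_sentences(text)) {
  ann <- annotations
  if (nrow(ann) == 0L) return(ann)
  validate_annotations(ann, text)
  if (nrow(rules) == 0L) return(ann)
  ann$negated <- FALSE

  rule_tokens <- strsplit(normalize_text(rules$phrase), " ", fixed = TRUE)

  for (si in seq_len(nrow(sentences))) {
    s0 <- sentences$start[si]; s1 <- sentences$end[si]
    sent <- substr(text, s0 + 1L, s1)
    toks <- tokenize(sent)
    if (nrow(toks) == 0L) next
    toks$start <- toks$start + s0
    toks$end <- toks$end + s0
    norm <- tolower(toks$surface)

    occ <- locate_triggers(norm, rules, rule_tokens)

    in_sent <- which(ann$start >= s0 & ann$end <= s1)
    if (!length(in_sent) || nrow(occ) == 0L) next
    pre <- occ[occ$category == "PRE_NEG", , drop = FALSE]
    post <- occ[occ$category == "POST_NEG", , drop = FALSE]
    stops <- occ$tstart[occ$category == "TERMINATION"]

    for (ai in in_sent) {
      first_tok <- which(toks$start >= ann$start[ai])[1]
      cover <- which(toks$start < ann$end[ai])
      last_tok <- if (length(cover)) max(cover) else NA_integer_
      if (is.na(first_tok) || is.na(last_tok)) next
      neg <- FALSE
      for (k in seq_len(nrow(pre))) {
        te <- pre$tend[k]
        if (first_tok <= te) next
        gap <- first_tok - te - 1L
        if (!is.na(pre$max_scope[k]) && gap >= pre$max_scope[k]) next
        if (any(stops > te & stops < first_tok)) next
        neg <- TRUE; break
      }
      if (!neg) for (k in seq_len(nrow(post))) {
        ts <- post$tstart[k]
        if (last_tok >= ts) next
        gap <- ts - last_tok - 1L
        if (!is.na(post$max_scope[k]) && gap >= post$max_scope[k]) next
        if (any(stops > last_tok & stops < ts)) next
        neg <- TRUE; break
      }
      if (neg) ann$negated[ai] <- TRUE
    }
  }
  ann
}

# Find trigger occurrences on a normalized token vector. Returns token-index
# ranges (1-based, inclusive) with category and scope, after longest-wins and
# pseudo-negation masking.
locate_triggers <- function(norm, rules, rule_tokens) {
  hits <- list()
  for (r in seq_along(rule_tokens)) {
    pt <- rule_tokens[[r]]
    L <- length(pt)
    if (L == 0L || L > length(norm)) next
    for (s in seq_len(length(norm) - L + 1L)) {
      if (all(norm[s:(s + L - 1L)] == pt)) {
        hits[[length(hits) + 1L]] <- data.frame(
          tstart = s, tend = s + L - 1L, category = rules$category[r],
          max_scope = rules$max_scope[r], len = L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(tstart = integer(), tend = integer(),
                      category = character(), max_scope = integer(),
                      len = integer(), stringsAsFactors = FALSE))
  }
  occ <- do.call(rbind, hits)
  # longest trigger wins at each start position
  occ <- occ[order(occ$tstart, -occ$len), , drop = FALSE]
  occ <- occ[!duplicated(occ$tstart), , drop = FALSE]
  # pseudo-negation masks overlapping pre/post triggers
  pseudo <- occ[occ$category == "PSEUDO_NEG", , drop = FALSE]
  if (nrow(pseudo)) {
    masked <- vapply(seq_len(nrow(occ)), function(i) {
      occ$category[i] %in% c("PRE_NEG", "POST_NEG") &&
        any(pseudo$tstart <= occ$tend[i] & occ$tstart[i] <= pseudo$tend)
    }, logical(1))
    occ <- occ[!masked, , drop = FALSE]
  }
  rownames(occ) <- NULL
  occ
}
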