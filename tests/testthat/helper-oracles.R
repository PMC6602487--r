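# Independent oracles and random-case generators, deliberately naive.

# Brute-force reachability: repeated relaxation over an edge list
# (parent -> child), no search structure shared with descendants().
brute_reachable <- function(edges, root) {
  reach <- root
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) return(sort(reach))
    reach <- nxt
  }
}

# Naive O(n * m) token-run scan: tests every lexicon entry against every
# token run of the text. Returns the full (partial-inclusive) match set.
naive_scan <- function(lexicon, text) {
  toks <- tokenize(text)
  cfg <- attr(lexicon, "config")
  norm <- if (cfg$case_sensitive) toks$surface else tolower(toks$surface)
  hits <- list()
  for (e in seq_len(nrow(lexicon))) {
    pt <- strsplit(lexicon$tokens[e], " ", fixed = TRUE)[[1]]
    L <- length(pt)
    if (L == 0 || L > length(norm)) next
    for (s in seq_len(length(norm) - L + 1L)) {
      if (all(norm[s:(s + L - 1L)] == pt)) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = toks$start[s], end = toks$end[s + L - 1L],
          hpo_id = lexicon$hpo_id[e], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      hpo_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out), , drop = FALSE]
  out <- out[order(out$start, out$end, out$hpo_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# word stock shared by random lexicons and texts so hits are frequent
oracle_vocab <- c("alpha", "beta", "gamma", "delta", "kappa", "sigma",
                  "omega", "zeta", "theta", "lambda", "mu", "nu")

random_lexicon <- function(max_entries = 30L, max_len = 4L) {
  n <- sample.int(max_entries, 1L)
  tokens <- vapply(seq_len(n), function(i) {
    paste(sample(oracle_vocab, sample.int(max_len, 1L), replace = TRUE),
          collapse = " ")
  }, character(1))
  ids <- sprintf("HP:%07d", sample.int(8L, n, replace = TRUE))
  make_lexicon(tokens, ids)
}

random_text <- function(max_tokens = 200L) {
  n <- sample.int(max_tokens + 1L, 1L) - 1L
  if (n == 0L) return("")
  words <- sample(c(oracle_vocab, "filler", "noise"), n, replace = TRUE)
  seps <- sample(c(" ", ", ", ". ", "  ", "; "), n, replace = TRUE)
  paste0(paste0(words, c(head(seps, -1L), "")), collapse = "")
}

random_mock_annotations <- function(text, n_max = 8L, engine = "mock") {
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(empty_annotations())
  n <- sample.int(n_max, 1L)
  i <- sample.int(nrow(toks), n, replace = TRUE)
  ann <- data.frame(
    start = toks$start[i], end = toks$end[i], surface = toks$surface[i],
    hpo_id = sprintf("HP:%07d", sample.int(6L, n, replace = TRUE)),
    hpo_name = "Mock", negated = sample(c(TRUE, FALSE), n, replace = TRUE),
    engine = engine, stringsAsFactors = FALSE)
  ann[!duplicated(ann[c("start", "end", "hpo_id")]), , drop = FALSE]
}

random_document <- function(doc_id = "doc") {
  text <- random_text(40L)
  ann <- if (nzchar(text)) random_mock_annotations(text) else
    empty_annotations()
  annotated_document(doc_id, if (nzchar(text)) text else "empty carrier",
                     if (nzchar(text)) ann else empty_annotations())
}
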