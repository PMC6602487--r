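# Tokenization, normalization, and token-run Aho-Corasick matching.

#' Normalization configuration
#'
#' @param case_sensitive Keep letter case? Default `FALSE` (case-folded
#'   matching, the usual choice for clinical text).
#' @return A list of class `normalizer_config`.
#' @export
normalizer_config <- function(case_sensitive = FALSE) {
  structure(list(case_sensitive = isTRUE(case_sensitive)),
            class = "normalizer_config")
}

#' Normalize a string for dictionary matching
#'
#' Case-folds (unless configured otherwise), turns every non-alphanumeric
#' character into a separator, and collapses runs of separators into single
#' spaces. Idempotent and deterministic.
#'
#' @param x Character vector.
#' @param config See [normalizer_config()].
#' @return Character vector of normalized strings ("" if no token survives).
#' @examples
#' normalize_text("Double-kidney")   # "double kidney"
#' @export
normalize_text <- function(x, config = normalizer_config()) {
  if (!config$case_sensitive) x <- tolower(x)
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize text into offset-carrying word tokens
#'
#' Tokens are maximal runs of Unicode letters/digits; punctuation and
#' whitespace separate tokens and are never part of one. Offsets are 0-based,
#' half-open character positions into the original string, so
#' `substr(text, start + 1, end)` recovers each surface form.
#'
#' @param text A single string (may be empty).
#' @return Data frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, gregexpr("[\\p{L}\\p{N}]+", text,
                                                 perl = TRUE))[[1]],
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Matching options
#'
#' @param longest_only Report only matches not strictly contained in a longer
#'   match (the "longest match only" policy). Default `TRUE`.
#' @param allow_partial Additionally report matches nested inside longer
#'   matches. Default `FALSE`.
#' @param case_sensitive Match with exact case. Requires a lexicon built with
#'   a case-sensitive [normalizer_config()]. Default `FALSE`.
#' @return A list of class `match_options`.
#' @export
match_options <- function(longest_only = TRUE, allow_partial = FALSE,
                          case_sensitive = FALSE) {
  structure(list(longest_only = isTRUE(longest_only),
                 allow_partial = isTRUE(allow_partial),
                 case_sensitive = isTRUE(case_sensitive)),
            class = "match_options")
}

#' Build an Aho-Corasick keyword automaton over a lexicon
#'
#' Patterns are the lexicon's normalized token sequences; the automaton's
#' alphabet is whole tokens, so matches are always token-boundary aligned and
#' no pattern can fire inside a longer word. Construction is the classic
#' goto/failure/output build, linear in total pattern length. The matcher is
#' immutable once built.
#'
#' @param lexicon An `hpo_lexicon` from [build_lexicon()] (must be non-empty).
#' @return An object of class `hpo_matcher`.
#' @export
build_automaton <- function(lexicon) {
  stopifnot(inherits(lexicon, "hpo_lexicon"))
  if (nrow(lexicon) == 0L) stop("cannot build a matcher from an empty lexicon",
                                call. = FALSE)
  pat_tokens <- strsplit(lexicon$tokens, " ", fixed = TRUE)

  edge <- new.env(parent = emptyenv())   # "node\rtoken" -> child id
  kids <- list(list())                   # per node: named list token -> child
  out <- list(integer(0))                # per node: pattern indices ending here
  n_nodes <- 1L

  for (p in seq_along(pat_tokens)) {
    node <- 1L
    for (tok in pat_tokens[[p]]) {
      key <- paste0(node, "\r", tok)
      nxt <- if (exists(key, envir = edge, inherits = FALSE))
        get(key, envir = edge) else NULL
      if (is.null(nxt)) {
        n_nodes <- n_nodes + 1L
        nxt <- n_nodes
        assign(key, nxt, envir = edge)
        kids[[node]][[tok]] <- nxt
        kids[[nxt]] <- list()
        out[[nxt]] <- integer(0)
      }
      node <- nxt
    }
    out[[node]] <- c(out[[node]], p)
  }

  # breadth-first failure links
  fail <- integer(n_nodes)
  fail[1L] <- 1L
  queue <- integer(0)
  for (tok in names(kids[[1L]])) {
    v <- kids[[1L]][[tok]]
    fail[v] <- 1L
    queue <- c(queue, v)
  }
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    for (tok in names(kids[[u]])) {
      v <- kids[[u]][[tok]]
      f <- fail[u]
      repeat {
        key <- paste0(f, "\r", tok)
        if (exists(key, envir = edge, inherits = FALSE)) {
          fail[v] <- get(key, envir = edge)
          break
        }
        if (f == 1L) { fail[v] <- 1L; break }
        f <- fail[f]
      }
      if (fail[v] == v) fail[v] <- 1L
      out[[v]] <- c(out[[v]], out[[fail[v]]])
      queue <- c(queue, v)
    }
  }

  structure(list(edge = edge, fail = fail, out = out,
                 pattern_len = lengths(pat_tokens),
                 lexicon = lexicon,
                 config = attr(lexicon, "config")),
            class = "hpo_matcher")
}

#' @export
print.hpo_matcher <- function(x, ...) {
  cat(sprintf("<hpo_matcher> %d patterns, %d automaton states\n",
              nrow(x$lexicon), length(x$fail)))
  invisible(x)
}

#' Find lexicon matches in text
#'
#' A lexicon entry matches iff its token sequence equals a contiguous run of
#' the document's normalized tokens (token-boundary aligned; never inside a
#' word). With the default `longest_only = TRUE, allow_partial = FALSE`, any
#' match whose character span is strictly contained in another match's span
#' is suppressed; same-span candidates for different concepts are all
#' reported. With `allow_partial = TRUE` nested matches are reported too.
#' Output is sorted by `(start, end, hpo_id)` and carries `engine = "dict"`.
#'
#' @param matcher From [build_automaton()].
#' @param text Document string.
#' @param opts See [match_options()].
#' @return Annotation data frame with columns `start`, `end`, `surface`,
#'   `hpo_id`, `hpo_name`, `negated`, `engine` (offsets 0-based, half-open).
#' @examples
#' onto <- parse_obo(system.file("extdata", "mini_hp.obo",
#'                               package = "phenotext"))
#' lex <- build_lexicon(onto, "HP:5000001")
#' m <- build_automaton(lex)
#' find_matches(m, "Patient presents short stature and fever.")
#' @export
find_matches <- function(matcher, text, opts = match_options()) {
  stopifnot(inherits(matcher, "hpo_matcher"))
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(empty_annotations())
  cfg <- matcher$config
  if (isTRUE(opts$case_sensitive) != isTRUE(cfg$case_sensitive)) {
    warning("case_sensitive option differs from the lexicon's ",
            "normalization config; the lexicon config wins", call. = FALSE)
  }
  norm <- if (cfg$case_sensitive) toks$surface else tolower(toks$surface)

  edge <- matcher$edge; fail <- matcher$fail; out <- matcher$out
  plen <- matcher$pattern_len
  hit_pat <- integer(0); hit_end <- integer(0)
  state <- 1L
  for (i in seq_along(norm)) {
    tok <- norm[[i]]
    repeat {
      key <- paste0(state, "\r", tok)
      if (exists(key, envir = edge, inherits = FALSE)) {
        state <- get(key, envir = edge)
        break
      }
      if (state == 1L) break
      state <- fail[state]
    }
    o <- out[[state]]
    if (length(o)) {
      hit_pat <- c(hit_pat, o)
      hit_end <- c(hit_end, rep.int(i, length(o)))
    }
  }
  if (!length(hit_pat)) return(empty_annotations())

  start_tok <- hit_end - plen[hit_pat] + 1L
  cs <- toks$start[start_tok]
  ce <- toks$end[hit_end]
  lex <- matcher$lexicon

  ann <- data.frame(start = cs, end = ce,
                    surface = substr(rep(text, length(cs)), cs + 1L, ce),
                    hpo_id = lex$hpo_id[hit_pat],
                    hpo_name = lex$hpo_name[hit_pat],
                    negated = FALSE, engine = "dict",
                    stringsAsFactors = FALSE)
  # identical (span, concept) through different entries (e.g. a synonym
  # normalizing like the name) collapse to one annotation
  ann <- ann[!duplicated(ann[c("start", "end", "hpo_id")]), , drop = FALSE]

  if (opts$longest_only && !opts$allow_partial) {
    keep <- !vapply(seq_len(nrow(ann)), function(i) {
      any(ann$start <= ann$start[i] & ann$end[i] <= ann$end &
            (ann$start < ann$start[i] | ann$end[i] < ann$end))
    }, logical(1))
    ann <- ann[keep, , drop = FALSE]
  }
  ann <- ann[order(ann$start, ann$end, ann$hpo_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' An empty annotation data frame
#'
#' @return Zero-row data frame with the standard annotation columns.
#' @export
empty_annotations <- function() {
  data.frame(start = integer(), end = integer(), surface = character(),
             hpo_id = character(), hpo_name = character(),
             negated = logical(), engine = character(),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, text, where = "annotations") {
  req <- c("start", "end", "surface", "hpo_id", "hpo_name", "negated",
           "engine")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(ann) == 0L) return(invisible(ann))
  n <- nchar(text)
  bad <- which(ann$start < 0L | ann$end > n | ann$start >= ann$end)
  if (length(bad)) {
    stop(sprintf("%s: annotation %d has span [%d,%d) outside text of length %d",
                 where, bad[1L], ann$start[bad[1L]], ann$end[bad[1L]], n),
         call. = FALSE)
  }
  slice <- substr(rep(text, nrow(ann)), ann$start + 1L, ann$end)
  mism <- which(slice != ann$surface)
  if (length(mism)) {
    stop(sprintf("%s: annotation %d surface '%s' != text slice '%s'",
                 where, mism[1L], ann$surface[mism[1L]], slice[mism[1L]]),
         call. = FALSE)
  }
  invisible(ann)
}
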