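# OBO parsing and ontology graph queries.

#' Parse an OBO flat file into an ontology object
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and keeps the tags that carry matching
#' signal: `id`, `name`, `synonym` (with its scope keyword), `is_a`, `xref`
#' and `is_obsolete`. All other tags, the file header, and non-`[Term]`
#' stanzas (`[Typedef]` etc.) are ignored. Obsolete terms are retained in the
#' ontology, flagged, so their cross-references stay queryable; they never
#' contribute lexicon entries (see [build_lexicon()]).
#'
#' @param file Path to an OBO file, or a connection.
#' @return An object of class `hpo_ontology`: a list with `terms` (a named
#'   list of term records, each with `id`, `name`, `synonyms` (data frame
#'   with columns `text`, `scope`), `parents`, `xrefs`, `obsolete`) and
#'   `n_terms`.
#' @examples
#' obo <- system.file("extdata", "mini_hp.obo", package = "phenotext")
#' onto <- parse_obo(obo)
#' onto$n_terms
#' @export
parse_obo <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  terms <- list()

  # locate stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)
  bounds <- c(stanza_starts, length(lines) + 1L)

  for (s in term_starts) {
    nxt <- min(bounds[bounds > s])
    body <- lines[seq.int(s + 1L, length.out = max(0L, nxt - s - 1L))]
    body_lines <- seq.int(s + 1L, length.out = max(0L, nxt - s - 1L))
    term <- parse_term_stanza(body, body_lines, stanza_line = s)
    if (!is.null(terms[[term$id]])) {
      stop(sprintf("duplicate term id '%s' at line %d", term$id, s),
           call. = FALSE)
    }
    terms[[term$id]] <- term
  }

  onto <- structure(
    list(terms = terms, n_terms = length(terms)),
    class = "hpo_ontology"
  )
  onto
}

parse_term_stanza <- function(body, body_lines, stanza_line) {
  tag_of <- function(x) sub(":.*$", "", x)
  val_of <- function(x) trimws(sub("^[^:]+:", "", x))
  keep <- grepl("^[A-Za-z_]+:", body)
  tags <- tag_of(body[keep])
  vals <- val_of(body[keep])

  id <- vals[tags == "id"]
  if (length(id) == 0L || !nzchar(id[1L])) {
    stop(sprintf("malformed [Term] stanza at line %d: missing id",
                 stanza_line), call. = FALSE)
  }
  id <- id[1L]

  name <- vals[tags == "name"]
  name <- if (length(name)) name[1L] else ""

  syn_raw <- vals[tags == "synonym"]
  synonyms <- parse_synonyms(syn_raw)

  parents <- vals[tags == "is_a"]
  # "HP:0000002 ! comment" -> keep the id only
  parents <- trimws(sub("!.*$", "", parents))
  parents <- parents[nzchar(parents)]

  xrefs <- vals[tags == "xref"]
  xrefs <- vapply(strsplit(xrefs, "\\s+"), `[[`, character(1), 1L)

  obsolete <- any(tags == "is_obsolete" & grepl("^true", vals))

  if (!obsolete && !nzchar(name)) {
    stop(sprintf("malformed [Term] stanza at line %d: empty name for '%s'",
                 stanza_line, id), call. = FALSE)
  }

  list(id = id, name = name, synonyms = synonyms,
       parents = unname(parents), xrefs = unname(xrefs),
       obsolete = obsolete)
}

parse_synonyms <- function(syn_raw) {
  if (length(syn_raw) == 0L) {
    return(data.frame(text = character(), scope = character(),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(syn_raw, regexec('^"(.*)"\\s*([A-Z_]*)', syn_raw))
  text <- vapply(m, function(g) if (length(g) >= 2) g[2] else "", character(1))
  scope <- vapply(m, function(g) if (length(g) >= 3) g[3] else "", character(1))
  # OBO default scope when the keyword is absent is RELATED
  scope[!scope %in% c("EXACT", "BROAD", "NARROW", "RELATED")] <- "RELATED"
  keep <- nzchar(text)
  data.frame(text = text[keep], scope = scope[keep], stringsAsFactors = FALSE)
}

#' @export
print.hpo_ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat(sprintf("<hpo_ontology> %d terms (%d obsolete)\n", x$n_terms, n_obs))
  invisible(x)
}

#' Transitive descendants of a term
#'
#' Returns the ids of all terms reachable from `root_id` by following `is_a`
#' edges downwards (i.e. the subtree rooted at `root_id`), including
#' `root_id` itself. Multi-parent terms are counted once. A cycle in the
#' `is_a` graph among the reachable terms raises an error.
#'
#' @param ontology An `hpo_ontology`.
#' @param root_id Term id present in the ontology.
#' @return Character vector of term ids (root first, then breadth-first
#'   discovery order).
#' @export
descendants <- function(ontology, root_id) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  if (is.null(ontology$terms[[root_id]])) {
    stop(sprintf("unknown term id '%s'", root_id), call. = FALSE)
  }
  children <- children_map(ontology)
  # iterative DFS with colors to surface is_a cycles among reachable nodes
  color <- new.env(parent = emptyenv())   # 1 = on stack, 2 = done
  out <- character(0)
  stack <- list(list(id = root_id, i = 0L))
  assign(root_id, 1L, envir = color)
  out <- c(out, root_id)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    kids <- children[[top$id]]
    if (is.null(kids)) kids <- character(0)
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      k <- kids[[top$i + 1L]]
      st <- if (exists(k, envir = color, inherits = FALSE))
        get(k, envir = color) else 0L
      if (st == 1L) {
        stop(sprintf("cycle detected in is_a graph involving '%s'", k),
             call. = FALSE)
      }
      if (st == 0L) {
        assign(k, 1L, envir = color)
        out <- c(out, k)
        stack[[length(stack) + 1L]] <- list(id = k, i = 0L)
      }
    } else {
      assign(top$id, 2L, envir = color)
      stack[[length(stack)]] <- NULL
    }
  }
  out
}

children_map <- function(ontology) {
  children <- new.env(parent = emptyenv())
  for (term in ontology$terms) {
    for (p in term$parents) {
      cur <- if (exists(p, envir = children, inherits = FALSE))
        get(p, envir = children) else character(0)
      assign(p, c(cur, term$id), envir = children)
    }
  }
  children
}

#' Build the matching lexicon for a subtree
#'
#' One lexicon entry is produced per term name and per synonym (whose scope
#' is in `include_scopes`) of every non-obsolete descendant of `root_id`.
#' Entries whose text normalizes to an empty token sequence are skipped with
#' a warning. Distinct concepts sharing a normalized string each keep their
#' own entry; disambiguation is the matcher's reporting concern.
#'
#' @param ontology An `hpo_ontology`.
#' @param root_id Subtree root; for the real HPO this is `HP:0000118`
#'   (phenotypic abnormality).
#' @param include_scopes Synonym scopes to admit. Defaults to all four.
#' @param config Normalization rules, see [normalizer_config()].
#' @return A data frame of class `hpo_lexicon` with columns `tokens`
#'   (space-joined normalized token sequence), `hpo_id`, `hpo_name`,
#'   `source` (`"NAME"` or `"SYNONYM"`), `source_scope` (`NA` for names) and
#'   `original_text`; attributes `root_id` and `config`.
#' @export
build_lexicon <- function(ontology, root_id,
                          include_scopes = c("EXACT", "BROAD",
                                             "NARROW", "RELATED"),
                          config = normalizer_config()) {
  stopifnot(inherits(ontology, "hpo_ontology"), length(include_scopes) > 0)
  in_scope <- descendants(ontology, root_id)

  rows <- list()
  for (id in in_scope) {
    term <- ontology$terms[[id]]
    if (term$obsolete) next
    cand <- data.frame(text = term$name, source = "NAME",
                       source_scope = NA_character_,
                       stringsAsFactors = FALSE)
    syn <- term$synonyms
    syn <- syn[syn$scope %in% include_scopes, , drop = FALSE]
    if (nrow(syn)) {
      cand <- rbind(cand, data.frame(text = syn$text, source = "SYNONYM",
                                     source_scope = syn$scope,
                                     stringsAsFactors = FALSE))
    }
    norm <- vapply(cand$text, normalize_text, character(1), config = config)
    empty <- !nzchar(norm)
    if (any(empty)) {
      warning(sprintf("term '%s': %d label(s) normalize to empty, skipped",
                      id, sum(empty)), call. = FALSE)
    }
    cand <- cand[!empty, , drop = FALSE]
    norm <- norm[!empty]
    if (!nrow(cand)) next
    rows[[id]] <- data.frame(tokens = unname(norm), hpo_id = id,
                             hpo_name = term$name, source = cand$source,
                             source_scope = cand$source_scope,
                             original_text = cand$text,
                             stringsAsFactors = FALSE)
  }
  lex <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tokens = character(), hpo_id = character(),
               hpo_name = character(), source = character(),
               source_scope = character(), original_text = character(),
               stringsAsFactors = FALSE)
  rownames(lex) <- NULL
  structure(lex, root_id = root_id, config = config,
            class = c("hpo_lexicon", "data.frame"))
}
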