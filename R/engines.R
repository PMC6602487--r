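# Engine contract, CUI->HPO mapping, ensemble-by-union, pipeline driver.

#' Wrap one engine's output for the ensemble
#'
#' @param engine_id Engine label, e.g. `"dict"`, `"metamap"`, `"ncbo"`.
#' @param annotations Annotation data frame; its `engine` column is set to
#'   `engine_id`.
#' @param text The document the annotations index into.
#' @return A list of class `engine_result`.
#' @export
engine_result <- function(engine_id, annotations, text) {
  stopifnot(is.character(engine_id), length(engine_id) == 1L)
  validate_annotations(annotations, text,
                       where = sprintf("engine '%s'", engine_id))
  if (nrow(annotations)) annotations$engine <- engine_id
  structure(list(engine_id = engine_id, annotations = annotations,
                 n_char = nchar(text)),
            class = "engine_result")
}

#' Map UMLS CUI annotations onto HPO concepts
#'
#' External annotators (MetaMap and relatives) emit UMLS Concept Unique
#' Identifiers. Each CUI maps to every ontology term that lists it as an
#' `xref` (one output annotation per mapped term, so a CUI shared by two
#' terms yields two same-span annotations). CUIs with no cross-reference hit
#' are dropped; the dropped count is reported via `message()`.
#'
#' @param cui_annotations Data frame with columns `start`, `end`, `cui`
#'   (e.g. `"UMLS:C0015967"`), `surface`.
#' @param ontology An `hpo_ontology` parsed with xrefs retained.
#' @param engine Label for the output annotations (default `"metamap"`).
#' @return Annotation data frame.
#' @export
map_cui_to_hpo <- function(cui_annotations, ontology, engine = "metamap") {
  stopifnot(inherits(ontology, "hpo_ontology"))
  if (nrow(cui_annotations) == 0L) return(empty_annotations())
  xref_map <- list()
  for (term in ontology$terms) {
    for (x in term$xrefs) xref_map[[x]] <- c(xref_map[[x]], term$id)
  }
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(cui_annotations))) {
    ids <- xref_map[[cui_annotations$cui[i]]]
    if (is.null(ids)) { dropped <- dropped + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      start = cui_annotations$start[i], end = cui_annotations$end[i],
      surface = cui_annotations$surface[i], hpo_id = ids,
      hpo_name = vapply(ids, function(id) ontology$terms[[id]]$name,
                        character(1)),
      negated = FALSE, engine = engine, stringsAsFactors = FALSE)
  }
  if (dropped) {
    message(sprintf("map_cui_to_hpo: %d CUI annotation(s) had no HPO xref",
                    dropped))
  }
  ann <- if (length(out)) do.call(rbind, out) else empty_annotations()
  rownames(ann) <- NULL
  ann
}

#' Combine engine results by set union
#'
#' The union keeps every distinct `(start, end, hpo_id)` triple reported by
#' any engine; this lowers the false-negative rate at the cost of false
#' positives. When the same triple is reported several times, the merged
#' annotation is negated only if every contributing copy is negated (the
#' union exists to maximize recall of asserted phenotypes). Output carries
#' `engine = "ensemble"` and is sorted by `(start, end, hpo_id)`.
#'
#' @param results List of [engine_result()] objects over the same document.
#' @return Annotation data frame.
#' @export
ensemble_union <- function(results) {
  stopifnot(is.list(results), length(results) > 0)
  ok <- vapply(results, inherits, logical(1), "engine_result")
  if (!all(ok)) stop("all elements must be engine_result objects",
                     call. = FALSE)
  n_char <- vapply(results, `[[`, numeric(1), "n_char")
  if (length(unique(n_char)) > 1L) {
    stop("engine results refer to documents of differing length",
         call. = FALSE)
  }
  all_ann <- do.call(rbind, lapply(results, `[[`, "annotations"))
  if (is.null(all_ann) || nrow(all_ann) == 0L) return(empty_annotations())
  key <- paste(all_ann$start, all_ann$end, all_ann$hpo_id, sep = "\r")
  negated <- tapply(all_ann$negated, key, all)
  first <- !duplicated(key)
  ann <- all_ann[first, , drop = FALSE]
  ann$negated <- as.logical(negated[key[first]])
  ann$engine <- "ensemble"
  ann <- ann[order(ann$start, ann$end, ann$hpo_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' The built-in dictionary engine
#'
#' @param matcher From [build_automaton()].
#' @param opts See [match_options()].
#' @return An engine: a list with `id` and a `run(text)` function.
#' @export
dict_engine <- function(matcher, opts = match_options()) {
  force(matcher); force(opts)
  structure(list(id = "dict",
                 run = function(text) find_matches(matcher, text, opts)),
            class = "phenotext_engine")
}

#' A replay engine serving pre-recorded annotations
#'
#' Stands in for a live external annotator: it replays annotations recorded
#' in a stand-off JSON file (one [write_standoff()] document per input
#' document id). Useful for testing pipelines that would otherwise call a
#' network service.
#'
#' @param path Stand-off JSON file for the document being processed.
#' @param id Engine label (default `"replay"`).
#' @return An engine usable with [run_pipeline()].
#' @export
replay_engine <- function(path, id = "replay") {
  force(path); force(id)
  structure(list(id = id,
                 run = function(text) {
                   doc <- read_standoff(path)
                   if (doc$text != text) {
                     stop("replay file text does not match the input document",
                          call. = FALSE)
                   }
                   doc$annotations
                 }),
            class = "phenotext_engine")
}

#' Run the full annotation pipeline
#'
#' Runs every configured engine on the text, applies negation detection to
#' each engine's annotations when enabled, and — when more than one engine is
#' configured — combines them with [ensemble_union()]. With a single engine
#' and negation off this is the identity on that engine's output. An engine
#' that raises an error contributes an empty result and a warning; the
#' pipeline continues.
#'
#' @param text Document string.
#' @param engines List of engines ([dict_engine()], [replay_engine()], or any
#'   list with fields `id` and `run(text)`).
#' @param negate Apply NegEx negation? Default `TRUE`.
#' @param rules Trigger rules for negation (default bundled set).
#' @return Annotation data frame.
#' @export
run_pipeline <- function(text, engines, negate = TRUE,
                         rules = read_trigger_rules()) {
  stopifnot(is.list(engines), length(engines) > 0)
  results <- lapply(engines, function(eng) {
    ann <- tryCatch(eng$run(text), error = function(e) {
      warning(sprintf("engine '%s' failed (%s); continuing with empty result",
                      eng$id, conditionMessage(e)), call. = FALSE)
      empty_annotations()
    })
    if (negate) ann <- apply_negex(text, ann, rules = rules)
    engine_result(eng$id, ann, text)
  })
  if (length(results) == 1L) results[[1]]$annotations
  else ensemble_union(results)
}
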