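# Stand-off JSON, CSV table, and Phenolyzer list exports.

#' Construct an annotated document
#'
#' @param doc_id Non-empty document identifier.
#' @param text Document string.
#' @param annotations Annotation data frame; spans are validated against
#'   `text`.
#' @return A list of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, text,
                               annotations = empty_annotations()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L)
  validate_annotations(annotations, text)
  rownames(annotations) <- NULL
  structure(list(doc_id = doc_id, text = text, annotations = annotations),
            class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document> '%s': %d chars, %d annotations\n",
              x$doc_id, nchar(x$text), nrow(x$annotations)))
  invisible(x)
}

standoff_cols <- c("start", "end", "surface", "hpo_id", "hpo_name",
                   "negated", "engine")

#' Write a document as stand-off JSON
#'
#' The stand-off format stores the annotations separately from the text they
#' apply to, referencing it by 0-based half-open character offsets. Schema:
#' top-level keys `doc_id`, `text`, `annotations`; each annotation an object
#' with keys `start`, `end`, `surface`, `hpo_id`, `hpo_name`, `negated`,
#' `engine`, in that order. UTF-8 throughout.
#'
#' @param doc An [annotated_document()].
#' @param path Output file path or connection.
#' @export
write_standoff <- function(doc, path) {
  stopifnot(inherits(doc, "annotated_document"))
  ann <- doc$annotations[, standoff_cols, drop = FALSE]
  payload <- list(doc_id = jsonlite::unbox(doc$doc_id),
                  text = jsonlite::unbox(doc$text),
                  annotations = ann)
  json <- jsonlite::toJSON(payload, dataframe = "rows", na = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(NULL)
}

#' Read a stand-off JSON document
#'
#' Validates the schema (all required keys present) and every annotation
#' (span within the text, surface equal to the text slice); a violation
#' raises an error naming the offending annotation index.
#'
#' @param path Stand-off JSON file path or connection.
#' @return An [annotated_document()].
#' @export
read_standoff <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  miss <- setdiff(c("doc_id", "text", "annotations"), names(obj))
  if (length(miss)) {
    stop(sprintf("stand-off file missing required key(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ann <- obj$annotations
  if (is.null(ann) || length(ann) == 0L || NROW(ann) == 0L) {
    ann <- empty_annotations()
  } else {
    if (!is.data.frame(ann)) ann <- as.data.frame(ann)
    miss <- setdiff(standoff_cols, names(ann))
    if (length(miss)) {
      stop(sprintf("stand-off annotations missing key(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    ann <- ann[, standoff_cols, drop = FALSE]
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
    ann$negated <- as.logical(ann$negated)
  }
  annotated_document(obj$doc_id, obj$text, ann)
}

#' Export a Phenolyzer-compatible phenotype list
#'
#' Phenolyzer (phenotype-driven gene prioritization) accepts a plain list of
#' phenotype terms, one per line. This emits the distinct concept names of a
#' document's annotations, lower-cased, in first-occurrence order, excluding
#' negated concepts unless asked. A concept is treated as negated only when
#' all of its annotations are negated.
#'
#' @param doc An [annotated_document()].
#' @param include_negated Keep negated concepts too? Default `FALSE`.
#' @param use_ids Emit HPO ids instead of names. Default `FALSE`.
#' @return Character vector of lines (possibly empty).
#' @export
export_phenolyzer <- function(doc, include_negated = FALSE,
                              use_ids = FALSE) {
  stopifnot(inherits(doc, "annotated_document"))
  ann <- doc$annotations
  if (nrow(ann) == 0L) return(character(0))
  if (!include_negated) {
    concept_neg <- tapply(ann$negated, ann$hpo_id, all)
    ann <- ann[!concept_neg[ann$hpo_id], , drop = FALSE]
  }
  if (nrow(ann) == 0L) return(character(0))
  vals <- if (use_ids) ann$hpo_id else tolower(ann$hpo_name)
  vals[!duplicated(vals)]
}

#' Export annotations from many documents as a CSV table
#'
#' One row per annotation, RFC 4180 quoting (fields containing commas,
#' quotes or newlines are quoted; embedded quotes doubled), with header
#' `doc_id,start,end,surface,hpo_id,hpo_name,negated,engine`.
#'
#' @param docs List of [annotated_document()] objects.
#' @param path Output file path or connection.
#' @export
export_table <- function(docs, path) {
  header <- c("doc_id", "start", "end", "surface", "hpo_id", "hpo_name",
              "negated", "engine")
  rows <- character(0)
  for (doc in docs) {
    ann <- doc$annotations
    if (nrow(ann) == 0L) next
    fields <- cbind(doc_id = doc$doc_id,
                    start = as.character(ann$start),
                    end = as.character(ann$end),
                    surface = ann$surface, hpo_id = ann$hpo_id,
                    hpo_name = ann$hpo_name,
                    negated = tolower(as.character(ann$negated)),
                    engine = ann$engine)
    rows <- c(rows, apply(fields, 1L, function(r)
      paste(vapply(r, csv_field, character(1)), collapse = ",")))
  }
  writeLines(c(paste(header, collapse = ","), rows), path, useBytes = TRUE)
  invisible(NULL)
}

csv_field <- function(x) {
  if (grepl('[",\n\r]', x)) paste0('"', gsub('"', '""', x), '"') else x
}
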