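# Precision/recall/F1 over distinct document-concept pairs.

#' Reduce a document to its distinct (doc_id, hpo_id) pairs
#'
#' Evaluation operates on distinct note-concept pairs: span offsets and
#' repeated mentions do not matter, only whether a concept was asserted for
#' a document. Negated annotations are excluded unless `include_negated`.
#'
#' @param doc An [annotated_document()].
#' @param include_negated Keep pairs whose only support is negated? Default
#'   `FALSE`.
#' @return Data frame with columns `doc_id`, `hpo_id`, one row per distinct
#'   pair.
#' @export
to_pairs <- function(doc, include_negated = FALSE) {
  stopifnot(inherits(doc, "annotated_document"))
  ann <- doc$annotations
  if (!include_negated) ann <- ann[!ann$negated, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(data.frame(doc_id = character(), hpo_id = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- data.frame(doc_id = doc$doc_id, hpo_id = ann$hpo_id,
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Build an EvalMetrics record from raw counts
#'
#' Conventions for degenerate inputs keep aggregation total: with nothing
#' predicted and nothing to find (`tp+fp = 0`, `fn = 0`) precision is 1.0;
#' with nothing predicted but gold pairs missed it is 0.0. Recall mirrors
#' this. F1 is the harmonic mean, 0 when `precision + recall = 0`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A list of class `eval_metrics` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
eval_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { if (fp == 0) 1 else 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d precision=%.3f recall=%.3f f1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score predicted pairs against a gold standard
#'
#' Set semantics: `tp` is the number of pairs in both sets, `fp` predicted
#' but not gold, `fn` gold but not predicted.
#'
#' @param predicted,gold Data frames with columns `doc_id`, `hpo_id`
#'   (duplicates collapse).
#' @return An [eval_metrics()] record.
#' @examples
#' p <- data.frame(doc_id = "n1", hpo_id = c("HP:1", "HP:2", "HP:4"))
#' g <- data.frame(doc_id = "n1", hpo_id = c("HP:1", "HP:2", "HP:3"))
#' evaluate_pairs(p, g)   # precision = recall = f1 = 2/3
#' @export
evaluate_pairs <- function(predicted, gold) {
  pk <- unique(paste(predicted$doc_id, predicted$hpo_id, sep = "\r"))
  gk <- unique(paste(gold$doc_id, gold$hpo_id, sep = "\r"))
  tp <- length(intersect(pk, gk))
  eval_metrics(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

#' Aggregate per-document metrics
#'
#' Micro-averaging pools the tp/fp/fn counts and recomputes the metrics;
#' macro-averaging takes the arithmetic mean of per-document precision,
#' recall and F1 (the count fields carry the pooled sums in both modes).
#'
#' @param per_doc List of [eval_metrics()] records.
#' @param mode `"micro"` (default) or `"macro"`.
#' @return An [eval_metrics()] record (macro: class `eval_metrics` with
#'   averaged rates).
#' @export
aggregate_metrics <- function(per_doc, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  stopifnot(is.list(per_doc))
  if (mode == "macro" && length(per_doc) == 0L) {
    stop("macro aggregation over an empty list", call. = FALSE)
  }
  tp <- sum(vapply(per_doc, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(per_doc, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(per_doc, `[[`, numeric(1), "fn"))
  if (mode == "micro") return(eval_metrics(tp, fp, fn))
  m <- eval_metrics(tp, fp, fn)
  m$precision <- mean(vapply(per_doc, `[[`, numeric(1), "precision"))
  m$recall <- mean(vapply(per_doc, `[[`, numeric(1), "recall"))
  m$f1 <- mean(vapply(per_doc, `[[`, numeric(1), "f1"))
  m
}

#' Read gold-standard pairs
#'
#' Accepts either a stand-off JSON document (pairs via [to_pairs()]) or a
#' two-column CSV `doc_id,hpo_id`.
#'
#' @param path Input file.
#' @param include_negated Passed to [to_pairs()] for stand-off input.
#' @return Data frame with columns `doc_id`, `hpo_id`.
#' @export
read_pairs <- function(path, include_negated = FALSE) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    return(to_pairs(read_standoff(path), include_negated = include_negated))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("doc_id", "hpo_id"), names(df))
  if (length(miss)) {
    stop(sprintf("pair file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[c("doc_id", "hpo_id")]
  df[!duplicated(df), , drop = FALSE]
}
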