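#' Gold-standard labels
#'
#' Reads a tab-separated label file with columns `case_id`, `lineage`
#' (`B`/`T`), `label` (`CLONAL`/`POLYCLONAL`) and optional `excluded`
#' (logical; cases removed after clinical re-review contribute to no
#' metric).
#'
#' @param source path to the TSV file.
#' @return a data frame of class `gold_labels`.
#' @export
read_gold_labels <- function(source) {
  # read everything as character: a bare "T" in the lineage column must not
  # type-infer to logical TRUE
  df <- utils::read.delim(source, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("case_id", "lineage", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gold label file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  df$case_id <- as.character(df$case_id)
  stopifnot(all(df$lineage %in% c("B", "T")),
            all(df$label %in% c("CLONAL", "POLYCLONAL")))
  class(df) <- c("gold_labels", class(df))
  df
}

#' Build a 2x2 confusion matrix from case calls and gold labels
#'
#' For each non-excluded label of the requested lineage, the matching case
#' result's lineage call is compared with the label: clonal vs clonal is a
#' true positive, a valid non-clonal call vs polyclonal a true negative,
#' and so on. Invalid calls are a third outcome, not a disagreement, and are
#' excluded from the 2x2 by default; `invalid_as_negative = TRUE` counts
#' them as non-clonal calls for sensitivity analyses.
#'
#' @param case_results list of `case_result` objects (see
#'   [aggregate_case()]).
#' @param labels a data frame as returned by [read_gold_labels()] (columns
#'   case_id, lineage, label, excluded).
#' @param lineage `"B"` or `"T"`.
#' @param invalid_as_negative count invalid calls as non-clonal instead of
#'   excluding them.
#' @return an object of class `confusion_matrix`: list with counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
build_confusion <- function(case_results, labels, lineage = c("B", "T"),
                            invalid_as_negative = FALSE) {
  lineage <- match.arg(lineage)
  if (is.null(labels$excluded)) labels$excluded <- FALSE
  labels <- labels[labels$lineage == lineage & !labels$excluded, , drop = FALSE]
  call_ids <- vapply(case_results, `[[`, character(1), "case_id")
  missing <- setdiff(labels$case_id, call_ids)
  if (length(missing)) {
    stop("no case result for gold-labelled case(s): ",
         paste(missing, collapse = ", "))
  }
  tp <- tn <- fp <- fn <- 0L
  field <- if (lineage == "B") "b_cell_call" else "t_cell_call"
  for (i in seq_len(nrow(labels))) {
    res <- case_results[[match(labels$case_id[i], call_ids)]]
    call <- res[[field]]
    if (is.na(call)) {
      stop("case ", labels$case_id[i], " has no ", lineage, "-lineage assays")
    }
    if (call == "INVALID") {
      if (!invalid_as_negative) next
      call <- "NEC"
    }
    positive_call <- call == "CLONAL"
    positive_label <- labels$label[i] == "CLONAL"
    if (positive_call && positive_label) tp <- tp + 1L
    else if (positive_call && !positive_label) fp <- fp + 1L
    else if (!positive_call && positive_label) fn <- fn + 1L
    else tn <- tn + 1L
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

# round half-up at `decimals` places (base round() is round-half-even, which
# does not match how the published accuracy tables were rounded)
.round_half_up <- function(x, decimals) {
  p <- 10^decimals
  floor(x * p + 0.5) / p
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`, each as a
#' percent rounded half-up to `decimals` places; a metric with a zero
#' denominator is undefined (`NA`).
#'
#' @param cm a [build_confusion()] result, or any list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @param decimals decimal places to round to (default 1).
#' @return an object of class `accuracy_metrics`: list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` in percent (or `NA`).
#' @examples
#' compute_metrics(list(tp = 17, tn = 8, fp = 2, fn = 1))
#' @export
compute_metrics <- function(cm, decimals = 1) {
  frac <- function(num, den) {
    if (den == 0) NA_real_ else .round_half_up(100 * num / den, decimals)
  }
  structure(list(
    sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    ppv = frac(cm$tp, cm$tp + cm$fp),
    npv = frac(cm$tn, cm$tn + cm$fn)
  ), class = "accuracy_metrics")
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Markdown accuracy report for several models
#'
#' Formats one row per named confusion matrix, mirroring the layout of a
#' published model-comparison table.
#'
#' @param matrices named list of confusion matrices.
#' @param decimals decimal places for the metrics.
#' @return a character vector of Markdown lines.
#' @export
metrics_markdown <- function(matrices, decimals = 1) {
  fmt <- function(v) if (is.na(v)) "—" else sprintf(paste0("%.", decimals, "f%%"), v)
  lines <- c(
    "| Model | #TP | #TN | #FP | #FN | Sensitivity | Specificity | PPV | NPV |",
    "|---|---|---|---|---|---|---|---|---|"
  )
  for (nm in names(matrices)) {
    cm <- matrices[[nm]]
    m <- compute_metrics(cm, decimals)
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %d | %d | %s | %s | %s | %s |",
      nm, cm$tp, cm$tn, cm$fp, cm$fn,
      fmt(m$sensitivity), fmt(m$specificity), fmt(m$ppv), fmt(m$npv)))
  }
  lines
}
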