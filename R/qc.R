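#' Negative-control check
#'
#' Every run carries a polyclonal negative control: the run fails if any
#' clone in the control exceeds `max_clone_pct` percent of total reads
#' (default 1%; the boundary is inclusive — a clone at exactly 1% passes).
#' Being percent-based, the check is invariant under uniform scaling of the
#' read counts.
#'
#' @param tbl the negative control as a normalized [clonotype_table()].
#' @param max_clone_pct maximum tolerated clone percent (default 1.0).
#' @return `TRUE` when no clone exceeds the ceiling.
#' @export
check_negative_control <- function(tbl, max_clone_pct = 1.0) {
  stopifnot(inherits(tbl, "clonotype_table"))
  counts <- tbl$records$read_count
  if (!length(counts)) return(TRUE)
  all(vapply(counts, .pct_le, logical(1),
             total = tbl$total_reads, thr = max_clone_pct))
}

#' Positive-control check
#'
#' The positive control is run through the active calling model at its
#' declared target and must come out clonal; an invalid (low-read) control
#' fails the check.
#'
#' @param tbl the positive control as a merged, normalized
#'   [clonotype_table()].
#' @param target assay target of the control (set on the table if missing).
#' @param cfg a [model_config()].
#' @return `TRUE` when the control is called clonal.
#' @export
check_positive_control <- function(tbl, target = tbl$target,
                                   cfg = model_config("roswell_park")) {
  stopifnot(inherits(tbl, "clonotype_table"))
  if (is.na(tbl$target) || !identical(tbl$target, target)) {
    tbl$target <- match.arg(target, ASSAY_TARGETS)
  }
  call_clonality(tbl, cfg)$call == "CLONAL"
}

#' Run-level quality gate
#'
#' Composes the run-level checks that must pass before any clinical sample
#' is analyzed: an adequate fraction of bases at or above Q30, a clean
#' negative control (no clone above 1% of total reads, and at least the
#' model's minimum read count — a near-empty control is not evidence of a
#' clean run), and a positive control that the active model calls clonal.
#'
#' @param q30_fraction fraction (0–1) of bases at or above Q30.
#' @param negative_control merged, normalized [clonotype_table()].
#' @param positive_control merged, normalized [clonotype_table()].
#' @param positive_control_target assay target of the positive control.
#' @param q30_threshold minimum acceptable `q30_fraction` (default 0.75, a
#'   configurable local acceptance choice).
#' @param cfg a [model_config()].
#' @param neg_max_clone_pct negative-control clone ceiling in percent.
#' @return an object of class `run_qc_result`: list with logicals
#'   `run_pass`, `q30_pass`, `negative_pass`, `positive_pass` and a
#'   character vector `messages` of failure reasons. `run_pass` is the
#'   conjunction of the three checks.
#' @export
evaluate_run <- function(q30_fraction, negative_control, positive_control,
                         positive_control_target = positive_control$target,
                         q30_threshold = 0.75,
                         cfg = model_config("roswell_park"),
                         neg_max_clone_pct = 1.0) {
  stopifnot(q30_fraction >= 0, q30_fraction <= 1)
  messages <- character(0)

  q30_pass <- q30_fraction >= q30_threshold
  if (!q30_pass) {
    messages <- c(messages, sprintf(
      "Q30 fraction %.3f below threshold %.3f", q30_fraction, q30_threshold))
  }

  neg_clean <- check_negative_control(negative_control, neg_max_clone_pct)
  neg_reads_ok <- negative_control$total_reads >= cfg$min_reads
  negative_pass <- neg_clean && neg_reads_ok
  if (!neg_clean) {
    messages <- c(messages, sprintf(
      "negative control has a clone above %.3g%% of total reads", neg_max_clone_pct))
  }
  if (!neg_reads_ok) {
    messages <- c(messages, sprintf(
      "negative control below the model minimum of %s reads",
      format(cfg$min_reads, scientific = FALSE)))
  }

  positive_pass <- check_positive_control(positive_control,
                                          positive_control_target, cfg)
  if (!positive_pass) {
    messages <- c(messages, "positive control was not called clonal")
  }

  structure(list(
    run_pass = q30_pass && negative_pass && positive_pass,
    q30_pass = q30_pass,
    negative_pass = negative_pass,
    positive_pass = positive_pass,
    messages = messages
  ), class = "run_qc_result")
}

#' @export
print.run_qc_result <- function(x, ...) {
  cat(sprintf("<run_qc_result> run_pass=%s (q30=%s, negative=%s, positive=%s)\n",
              x$run_pass, x$q30_pass, x$negative_pass, x$positive_pass))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}
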