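#' @title Clonality calls
#' @description Per-assay clonality classification. Every caller takes a
#'   merged, normalized [clonotype_table()] and a [model_config()] and returns
#'   an `assay_call` carrying the classification and an audit trail of which
#'   decision-tree rule fired.
#' @name calling
NULL

CALL_LEVELS <- c("CLONAL", "NEC", "INVALID", "OLIGOCLONAL", "POLYCLONAL_MINOR")

new_assay_call <- function(tbl, cfg, call, fired_rule,
                           dominant_pcts = numeric(0),
                           background_pct = NA_real_) {
  stopifnot(call %in% CALL_LEVELS)
  structure(list(
    sample_id = tbl$sample_id,
    target = tbl$target,
    call = call,
    dominant_pcts = as.numeric(dominant_pcts),
    background_pct = as.numeric(background_pct),
    fired_rule = fired_rule,
    model_name = cfg$model_name
  ), class = "assay_call")
}

#' @export
print.assay_call <- function(x, ...) {
  cat(sprintf("<assay_call> %s %s [%s] %s (rule: %s)\n",
              x$sample_id, x$target, x$model_name, x$call, x$fired_rule))
  if (length(x$dominant_pcts)) {
    cat("  dominant %:", paste(sprintf("%.3g", x$dominant_pcts), collapse = ", "), "\n")
  }
  if (!is.na(x$background_pct)) {
    cat(sprintf("  background %%: %.4g\n", x$background_pct))
  }
  invisible(x)
}

# read count at a rank, 0 when the rank does not exist
.count_at <- function(counts, r) if (r <= length(counts)) counts[r] else 0
.pct_at <- function(rec, r) if (r <= nrow(rec)) rec$pct_total[r] else 0

# Percent comparisons are done on read counts against threshold * total so
# that pct-threshold boundaries are decided exactly, not through the float
# division 100*count/total.
.pct_ge <- function(count, total, thr) total > 0 && count * 100 >= thr * total
.pct_le <- function(count, total, thr) total > 0 && count * 100 <= thr * total

# Median read count of the qualifying background clones (ranks 3-10 with
# pct <= clone_max_pct), or NA when fewer than min_n qualify.
.rp_background_count <- function(tbl, clone_max_pct, min_n = 3) {
  counts <- tbl$records$read_count
  total <- tbl$total_reads
  ranks <- seq.int(3, min(10, length(counts)))
  if (length(counts) < 3) return(NA_real_)
  qual <- counts[ranks][vapply(counts[ranks], .pct_le, logical(1),
                               total = total, thr = clone_max_pct)]
  if (length(qual) < min_n) return(NA_real_)
  stats::median(qual)
}

#' Roswell Park polyclonal background
#'
#' Considers the clones ranked 3 through 10 and selects those whose percent
#' of total reads is at most `clone_max_pct`. If fewer than three qualify the
#' background is undefined (`NA`); otherwise it is the median of the
#' qualifying clones' percent values.
#'
#' @param tbl a merged, normalized [clonotype_table()].
#' @param clone_max_pct background clone ceiling in percent (1.0 for the IGH
#'   framework assays, 1.25 for IGK/TRG/TRB).
#' @return the background in percent, or `NA` when undefined.
#' @export
rp_polyclonal_background <- function(tbl, clone_max_pct) {
  m <- .rp_background_count(tbl, clone_max_pct)
  if (is.na(m) || tbl$total_reads <= 0) return(NA_real_)
  100 * m / tbl$total_reads
}

# Read count of the first clone in ranks 2..10 whose count is at most half
# the clone ranked immediately above it; NA when no such clone exists.
.ns_background_count <- function(tbl) {
  counts <- tbl$records$read_count
  hi <- min(10, length(counts))
  if (hi < 2) return(NA_real_)
  for (r in 2:hi) {
    if (2 * counts[r] <= counts[r - 1]) return(counts[r])
  }
  NA_real_
}

#' Nollet/Schumaker polyclonal background
#'
#' Scans the ten most frequent merged clones in rank order and returns the
#' percent of the first clone whose frequency is at most half that of the
#' clone ranked immediately above it (the first two-fold drop). `NA` when no
#' such drop occurs within the top 10 — the original publications give no
#' guidance for that case.
#'
#' @param tbl a merged, normalized [clonotype_table()] with >= 2 records.
#' @return the background in percent, or `NA` when undefined.
#' @export
ns_polyclonal_background <- function(tbl) {
  m <- .ns_background_count(tbl)
  if (is.na(m) || tbl$total_reads <= 0) return(NA_real_)
  100 * m / tbl$total_reads
}

#' Invivoscribe (manufacturer) clonality call
#'
#' Invalid below 20,000 total reads. Clonal when the rank-1 or rank-2 clone
#' is at least 2.5% of total reads and at least 10x the third most frequent
#' clone (treated as 0 when absent); otherwise no evidence of clonality.
#'
#' @param tbl a merged, normalized [clonotype_table()].
#' @param cfg a `model_config("invivoscribe")`.
#' @return an `assay_call`.
#' @export
call_invivoscribe <- function(tbl, cfg = model_config("invivoscribe")) {
  rec <- tbl$records; counts <- rec$read_count; total <- tbl$total_reads
  if (total < cfg$min_reads) {
    return(new_assay_call(tbl, cfg, "INVALID", "read_gate"))
  }
  if (nrow(rec) == 0) {
    return(new_assay_call(tbl, cfg, "NEC", "zero_clones"))
  }
  c3 <- .count_at(counts, 3)
  bkg_pct <- 100 * c3 / total
  for (r in 1:2) {
    cr <- .count_at(counts, r)
    if (cr > 0 && .pct_ge(cr, total, cfg$dominant_pct) &&
        cr >= cfg$background_ratio * c3) {
      return(new_assay_call(tbl, cfg, "CLONAL", "dominant_clone",
                            dominant_pcts = .pct_at(rec, r),
                            background_pct = bkg_pct))
    }
  }
  new_assay_call(tbl, cfg, "NEC", "no_dominant_clone", background_pct = bkg_pct)
}

#' MSK (Arcila) clonality call
#'
#' Invalid below 30,000 total reads. For samples with at least 100,000 reads
#' a dominant clone must reach 2.5% of total reads and 10x the rank-3
#' background; below 100,000 reads the thresholds are 5% and 20x. The
#' dominant block is the maximal run of leading ranks each meeting the
#' percent threshold and the ratio against the first clone after the block;
#' three or more dominant clones with more than 100,000 reads is
#' oligoclonal. Otherwise clonal when the rank-1 (hence possibly rank-2)
#' clone is dominant against the rank-3 background, else no evidence of
#' clonality.
#'
#' @param tbl a merged, normalized [clonotype_table()] (MSK merge dialect).
#' @param cfg a `model_config("msk")`.
#' @return an `assay_call`.
#' @export
call_msk <- function(tbl, cfg = model_config("msk")) {
  rec <- tbl$records; counts <- rec$read_count; total <- tbl$total_reads
  if (total < cfg$min_reads) {
    return(new_assay_call(tbl, cfg, "INVALID", "read_gate"))
  }
  if (nrow(rec) == 0) {
    return(new_assay_call(tbl, cfg, "NEC", "zero_clones"))
  }
  if (total >= cfg$high_read_cutoff) {
    thr <- cfg$dominant_pct_high; ratio <- cfg$background_ratio_high
    branch <- "high_reads"
  } else {
    thr <- cfg$dominant_pct_low; ratio <- cfg$background_ratio_low
    branch <- "low_reads"
  }
  c3 <- .count_at(counts, 3)
  bkg_pct <- 100 * c3 / total
  # maximal leading dominant block: counts are sorted, so block size k is
  # feasible iff the k-th clone meets the percent gate and is >= ratio x the
  # first clone after the block
  k_max <- 0L
  for (k in seq_len(nrow(rec))) {
    if (.pct_ge(counts[k], total, thr) &&
        counts[k] >= ratio * .count_at(counts, k + 1)) {
      k_max <- k
    }
  }
  if (k_max >= cfg$oligoclonal_min_dominant && total > cfg$high_read_cutoff) {
    return(new_assay_call(tbl, cfg, "OLIGOCLONAL",
                          paste0("oligoclonal_", branch),
                          dominant_pcts = rec$pct_total[seq_len(k_max)],
                          background_pct = bkg_pct))
  }
  dom <- integer(0)
  for (r in 1:2) {
    cr <- .count_at(counts, r)
    if (cr > 0 && .pct_ge(cr, total, thr) && cr >= ratio * c3) dom <- c(dom, r)
  }
  if (length(dom)) {
    return(new_assay_call(tbl, cfg, "CLONAL", paste0("dominant_", branch),
                          dominant_pcts = rec$pct_total[dom],
                          background_pct = bkg_pct))
  }
  new_assay_call(tbl, cfg, "NEC", paste0("no_dominant_", branch),
                 background_pct = bkg_pct)
}

#' Nollet/Schumaker clonality call
#'
#' Invalid below the model read gate (1,000; 20,000 for the modified
#' variant). Clonal when the rank-1 or rank-2 clone is at least 4% of total
#' reads and at least 4.5x the first-two-fold-drop background (which must be
#' defined). Otherwise "polyclonal" (reported here as NEC) when no clone
#' exceeds 2% of total reads, else "polyclonal with minor clonal
#' rearrangements" — including the case where the background is undefined
#' but some clone exceeds 2%.
#'
#' @param tbl a merged, normalized [clonotype_table()].
#' @param cfg a `model_config("nollet_schumaker")` or
#'   `model_config("ns_modified")`.
#' @return an `assay_call`.
#' @export
call_nollet_schumaker <- function(tbl, cfg = model_config("nollet_schumaker")) {
  rec <- tbl$records; counts <- rec$read_count; total <- tbl$total_reads
  if (total < cfg$min_reads) {
    return(new_assay_call(tbl, cfg, "INVALID", "read_gate"))
  }
  if (nrow(rec) == 0) {
    return(new_assay_call(tbl, cfg, "NEC", "zero_clones"))
  }
  bkg <- .ns_background_count(tbl)
  bkg_pct <- if (is.na(bkg)) NA_real_ else 100 * bkg / total
  if (!is.na(bkg)) {
    for (r in 1:2) {
      cr <- .count_at(counts, r)
      if (cr > 0 && .pct_ge(cr, total, cfg$dominant_pct) &&
          cr >= cfg$background_ratio * bkg) {
        return(new_assay_call(tbl, cfg, "CLONAL", "dominant_clone",
                              dominant_pcts = .pct_at(rec, r),
                              background_pct = bkg_pct))
      }
    }
  }
  all_low <- all(vapply(counts, .pct_le, logical(1),
                        total = total, thr = cfg$polyclonal_max_pct))
  if (all_low) {
    return(new_assay_call(tbl, cfg, "NEC", "polyclonal", background_pct = bkg_pct))
  }
  new_assay_call(tbl, cfg, "POLYCLONAL_MINOR", "minor_clonal_rearrangements",
                 background_pct = bkg_pct)
}

# shared body of the Roswell Park B and T decision trees; the two differ in
# bypass threshold, background clone ceiling, final threshold, and step count
.call_roswell <- function(tbl, cfg, bypass_pct, clone_max_pct, final_pct,
                          step_final) {
  rec <- tbl$records; counts <- rec$read_count; total <- tbl$total_reads
  if (total < cfg$min_reads) {
    return(new_assay_call(tbl, cfg, "INVALID", "step1"))
  }
  top2 <- .count_at(counts, 1) + .count_at(counts, 2)
  top2_pcts <- rec$pct_total[seq_len(min(2, nrow(rec)))]
  if (.pct_ge(top2, total, bypass_pct)) {
    return(new_assay_call(tbl, cfg, "CLONAL", "step2", dominant_pcts = top2_pcts))
  }
  m <- .rp_background_count(tbl, clone_max_pct, cfg$min_background_clones)
  if (is.na(m)) {
    return(new_assay_call(tbl, cfg, "NEC", "step3", dominant_pcts = top2_pcts))
  }
  bkg_pct <- 100 * m / total
  if (!(top2 >= cfg$background_ratio * m)) {
    return(new_assay_call(tbl, cfg, "NEC", "step4",
                          dominant_pcts = top2_pcts, background_pct = bkg_pct))
  }
  call <- if (.pct_ge(top2, total, final_pct)) "CLONAL" else "NEC"
  new_assay_call(tbl, cfg, call, step_final,
                 dominant_pcts = top2_pcts, background_pct = bkg_pct)
}

#' Roswell Park B-cell clonality call
#'
#' The B-cell decision tree, applied per assay (IGH FR1/FR2/FR3, IGK):
#' step 1 — invalid below 20,000 total reads; step 2 — clonal when the top
#' two merged clones together reach 30% of total reads; step 3 — the
#' polyclonal background is the median of clones ranked 3–10 at <= 1%
#' (<= 1.25% for IGK); fewer than three such clones is no evidence of
#' clonality; step 4 — no evidence of clonality unless the top-two sum is at
#' least 10x the background; steps 5–7 — clonal when the top-two sum reaches
#' 5% (IGK, step 6) or 2.5% (FR assays, step 7), else no evidence of
#' clonality. `fired_rule` records the step that decided the call.
#'
#' @param tbl a merged, normalized [clonotype_table()] with a B-lineage
#'   target.
#' @param cfg a `model_config("roswell_park")`.
#' @return an `assay_call`.
#' @export
call_roswell_b <- function(tbl, cfg = model_config("roswell_park")) {
  stopifnot(tbl$target %in% B_TARGETS)
  is_igk <- tbl$target == "IGK"
  .call_roswell(
    tbl, cfg,
    bypass_pct = cfg$bypass_pct_b,
    clone_max_pct = if (is_igk) cfg$background_clone_max_pct_other
                    else cfg$background_clone_max_pct_fr,
    final_pct = if (is_igk) cfg$final_pct_igk else cfg$final_pct_fr,
    step_final = if (is_igk) "step6" else "step7"
  )
}

#' Roswell Park T-cell clonality call
#'
#' The T-cell decision tree, applied per assay (TRG, TRB): step 1 — invalid
#' below 20,000 total reads; step 2 — clonal when the top two merged clones
#' together reach 50% of total reads; step 3 — the polyclonal background is
#' the median of clones ranked 3–10 at <= 1.25%; fewer than three such
#' clones is no evidence of clonality; step 4 — no evidence of clonality
#' unless the top-two sum is at least 10x the background; step 5 — clonal
#' when the top-two sum reaches 5%, else no evidence of clonality.
#'
#' @param tbl a merged, normalized [clonotype_table()] with a T-lineage
#'   target.
#' @param cfg a `model_config("roswell_park")`.
#' @return an `assay_call`.
#' @export
call_roswell_t <- function(tbl, cfg = model_config("roswell_park")) {
  stopifnot(tbl$target %in% T_TARGETS)
  .call_roswell(
    tbl, cfg,
    bypass_pct = cfg$bypass_pct_t,
    clone_max_pct = cfg$background_clone_max_pct_other,
    final_pct = cfg$final_pct_t,
    step_final = "step5"
  )
}

#' Call clonality for one assay under any configured model
#'
#' Dispatches to the model named in `cfg`; the Roswell Park model routes by
#' the table's target lineage.
#'
#' @param tbl a merged, normalized [clonotype_table()] whose `target` is set.
#' @param cfg a [model_config()].
#' @return an `assay_call`.
#' @export
call_clonality <- function(tbl, cfg = model_config("roswell_park")) {
  stopifnot(inherits(cfg, "model_config"))
  switch(cfg$model_name,
    invivoscribe = call_invivoscribe(tbl, cfg),
    msk = call_msk(tbl, cfg),
    nollet_schumaker = call_nollet_schumaker(tbl, cfg),
    ns_modified = call_nollet_schumaker(tbl, cfg),
    roswell_park = if (target_lineage(tbl$target) == "B") {
      call_roswell_b(tbl, cfg)
    } else {
      call_roswell_t(tbl, cfg)
    }
  )
}

#' Aggregate per-assay calls to a case-level result
#'
#' A patient's lineage result is clonal if any constituent assay for that
#' lineage is clonal (any of IGH FR1/FR2/FR3/IGK for B; TRG/TRB for T).
#' Otherwise the lineage is a valid negative (NEC) if any assay produced a
#' valid non-clonal result (NEC, oligoclonal, or polyclonal with minor
#' clonal rearrangements all count as valid non-clonal), and invalid only
#' when every assay of the lineage failed. A lineage with no assays is
#' reported as `NA`.
#'
#' @param calls list of `assay_call` objects for one case.
#' @param case_id case identifier.
#' @return an object of class `case_result` with elements `case_id`,
#'   `b_cell_call`, `t_cell_call`, `assay_calls`.
#' @export
aggregate_case <- function(calls, case_id) {
  stopifnot(all(vapply(calls, inherits, logical(1), "assay_call")))
  lineage_call <- function(lineage_targets) {
    sub <- Filter(function(x) x$target %in% lineage_targets, calls)
    if (!length(sub)) return(NA_character_)
    cs <- vapply(sub, `[[`, character(1), "call")
    if (any(cs == "CLONAL")) return("CLONAL")
    if (any(cs %in% c("NEC", "OLIGOCLONAL", "POLYCLONAL_MINOR"))) return("NEC")
    "INVALID"
  }
  structure(list(
    case_id = as.character(case_id),
    b_cell_call = lineage_call(B_TARGETS),
    t_cell_call = lineage_call(T_TARGETS),
    assay_calls = calls
  ), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s  B: %s  T: %s  (%d assays)\n",
              x$case_id, x$b_cell_call, x$t_cell_call, length(x$assay_calls)))
  invisible(x)
}
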