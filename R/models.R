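#' Configure a clonality-calling model
#'
#' Builds the numeric threshold set of one rule set. Five model variants are
#' available:
#'
#' * `roswell_park` — the decision-tree model: sample read gate 20,000; a
#'   top-two bypass (combined top-two percent >= 30 for the IGH framework
#'   assays and IGK, >= 50 for TRG/TRB, per the published step lists); a
#'   polyclonal background defined as the median of clones ranked 3–10 whose
#'   percent of total reads is <= 1% (IGH FR1/FR2/FR3) or <= 1.25% (IGK,
#'   TRG, TRB), requiring at least 3 such clones; a 10x top-two-to-background
#'   ratio; and final top-two percent thresholds of 2.5 (FR assays) or 5
#'   (IGK, TRG, TRB).
#' * `invivoscribe` — manufacturer recommendation: read gate 20,000; clonal
#'   when a leading clone is >= 2.5% of total reads and >= 10x the
#'   third-most-frequent clone.
#' * `msk` — read gate 30,000; for >= 100,000 reads a dominant clone is
#'   >= 2.5% and >= 10x the rank-3 background, otherwise >= 5% and >= 20x;
#'   oligoclonal when >= 3 dominant clones and > 100,000 reads. Uses the
#'   wider merge dialect (clones differing by < 5 nucleotides merge).
#' * `nollet_schumaker` — read gate 1,000; dominant clone >= 4% and >= 4.5x a
#'   background defined as the first clone in the top 10 whose percent is at
#'   most half the clone ranked immediately above it; "polyclonal" when no
#'   clone exceeds 2%; otherwise "polyclonal with minor clonal
#'   rearrangements".
#' * `ns_modified` — `nollet_schumaker` with the more typical read gate of
#'   20,000.
#'
#' Any threshold can be overridden through `...` (unknown keys are
#' rejected), e.g. `model_config("roswell_park", bypass_pct_igk = 50)`
#' recovers the tabulated 50% IGK bypass variant.
#'
#' @param model_name one of `"roswell_park"`, `"invivoscribe"`, `"msk"`,
#'   `"nollet_schumaker"`, `"ns_modified"`.
#' @param ... named threshold overrides.
#' @return an object of class `model_config`.
#' @export
model_config <- function(model_name = c("roswell_park", "invivoscribe", "msk",
                                        "nollet_schumaker", "ns_modified"),
                         ...) {
  model_name <- match.arg(model_name)
  cfg <- switch(model_name,
    invivoscribe = list(
      min_reads = 20000,
      dominant_pct = 2.5,
      background_ratio = 10,
      merge_policy = merge_policy()
    ),
    msk = list(
      min_reads = 30000,
      high_read_cutoff = 100000,
      dominant_pct_low = 5, background_ratio_low = 20,
      dominant_pct_high = 2.5, background_ratio_high = 10,
      oligoclonal_min_dominant = 3,
      merge_policy = merge_policy(max_mismatch = 4L)
    ),
    nollet_schumaker = list(
      min_reads = 1000,
      dominant_pct = 4,
      background_ratio = 4.5,
      polyclonal_max_pct = 2,
      merge_policy = merge_policy()
    ),
    ns_modified = list(
      min_reads = 20000,
      dominant_pct = 4,
      background_ratio = 4.5,
      polyclonal_max_pct = 2,
      merge_policy = merge_policy()
    ),
    roswell_park = list(
      min_reads = 20000,
      bypass_pct_b = 30, bypass_pct_t = 50,
      background_clone_max_pct_fr = 1.0,
      background_clone_max_pct_other = 1.25,
      min_background_clones = 3,
      background_ratio = 10,
      final_pct_fr = 2.5, final_pct_igk = 5, final_pct_t = 5,
      merge_policy = merge_policy()
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown model_config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  cfg$model_name <- model_name
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s\n", x$model_name))
  flat <- x[!vapply(x, is.list, logical(1))]
  flat$model_name <- NULL
  for (k in names(flat)) cat(sprintf("  %-28s %s\n", k, format(flat[[k]])))
  mp <- x$merge_policy
  cat(sprintf("  merge: top %d vs pool %d, max_mismatch %d (%s)\n",
              mp$top_n, mp$pool_n, mp$max_mismatch, mp$length_mode))
  invisible(x)
}
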