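#' Specification for one synthetic clonotype sample
#'
#' The simulator emulates the phenotypes seen in clinical clonality testing:
#'
#' * `polyclonal` — many distinct clones represented evenly at very low
#'   frequency (default 500 background clones over 100,000 reads);
#' * `monoclonal` / `biclonal` — one or two dominant clones at fixed target
#'   fractions over a polyclonal background;
#' * `restricted` — a paucity of lymphocytes: few unique clones (default 8),
#'   none dominant, so most clones sit at artificially high percent;
#' * `low_reads` — a failed sample below the 20,000-read acceptance gate.
#'
#' Background clone frequencies are drawn from a symmetric Dirichlet with
#' parameter `background_concentration` (larger = flatter), scaled to
#' `1 - sum(dominant_fractions)`; dominant clones sit at their exact target
#' fractions; read counts are multinomial with `total_reads` trials. With
#' probability `near_duplicate_rate` each dominant clone emits a satellite
#' clone — its own sequence mutated at 1–2 random positions, carrying 10% of
#' the dominant clone's probability mass — to exercise the merge step.
#'
#' @param phenotype one of `polyclonal`, `monoclonal`, `biclonal`,
#'   `restricted`, `low_reads`.
#' @param n_background_clones number of background clones (phenotype default
#'   when `NULL`; must be <= 12 for `restricted`).
#' @param dominant_fractions dominant clone fractions of total reads
#'   (length 1 for monoclonal, 2 for biclonal, empty otherwise; sum < 1).
#' @param total_reads multinomial trial count (phenotype default when
#'   `NULL`).
#' @param background_concentration symmetric Dirichlet parameter (default 5).
#' @param near_duplicate_rate per-dominant-clone satellite probability.
#' @param sequence_length length of the simulated clonotype sequences.
#' @param seed RNG seed; identical specs with identical seeds generate
#'   identical samples.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(phenotype = c("polyclonal", "monoclonal", "biclonal",
                                         "restricted", "low_reads"),
                           n_background_clones = NULL,
                           dominant_fractions = NULL,
                           total_reads = NULL,
                           background_concentration = NULL,
                           near_duplicate_rate = 0,
                           sequence_length = 35L,
                           seed = 1L) {
  phenotype <- match.arg(phenotype)
  defaults <- switch(phenotype,
    polyclonal = list(n = 500L, dom = numeric(0), reads = 100000L, conc = 5),
    monoclonal = list(n = 500L, dom = 0.40, reads = 100000L, conc = 5),
    biclonal = list(n = 500L, dom = c(0.25, 0.20), reads = 100000L, conc = 5),
    # restricted means few clones at artificially high percent with NONE
    # dominant: a flat Dirichlet keeps the top clones below dominance
    restricted = list(n = 8L, dom = numeric(0), reads = 100000L, conc = 25),
    low_reads = list(n = 500L, dom = numeric(0), reads = 10000L, conc = 5)
  )
  background_concentration <- background_concentration %||% defaults$conc
  n_background_clones <- as.integer(n_background_clones %||% defaults$n)
  dominant_fractions <- as.numeric(dominant_fractions %||% defaults$dom)
  total_reads <- as.integer(total_reads %||% defaults$reads)

  n_dom_expected <- switch(phenotype, monoclonal = 1L, biclonal = 2L, 0L)
  if (length(dominant_fractions) != n_dom_expected) {
    stop(sprintf("phenotype '%s' requires exactly %d dominant fraction(s)",
                 phenotype, n_dom_expected))
  }
  if (sum(dominant_fractions) >= 1) {
    stop("dominant fractions must sum to less than 1")
  }
  if (phenotype == "restricted" && n_background_clones > 12L) {
    stop("restricted phenotype requires n_background_clones <= 12")
  }
  stopifnot(n_background_clones >= 1L, total_reads >= 1L,
            background_concentration > 0, near_duplicate_rate >= 0,
            near_duplicate_rate <= 1, sequence_length >= 5L)
  structure(list(
    phenotype = phenotype,
    n_background_clones = n_background_clones,
    dominant_fractions = dominant_fractions,
    total_reads = total_reads,
    background_concentration = background_concentration,
    near_duplicate_rate = near_duplicate_rate,
    sequence_length = as.integer(sequence_length),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# n distinct random nucleotide sequences of the given length
.random_sequences <- function(n, len) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  seqs <- draw(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- draw(length(dup))
  }
  seqs
}

# mutate `seq` at n_mut random positions (guaranteed substitutions)
.mutate_sequence <- function(seq, n_mut) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic clonotype table with known truth
#'
#' @param spec a [synthetic_spec()].
#' @param sample_id sample identifier for the generated table.
#' @param target assay target to stamp on the table.
#' @return a list with elements `table` (a [clonotype_table()] whose read
#'   counts sum exactly to `spec$total_reads`) and `truth` (`"CLONAL"` for
#'   monoclonal/biclonal specs, `"POLYCLONAL"` otherwise).
#' @examples
#' s <- synthetic_spec("monoclonal", seed = 7)
#' generate_sample(s, "S1", "TRG")$table
#' @export
generate_sample <- function(spec, sample_id = "synthetic", target = "TRG") {
  stopifnot(inherits(spec, "synthetic_spec"))
  target <- match.arg(target, ASSAY_TARGETS)
  .with_seed(spec$seed, {
    dom <- spec$dominant_fractions
    n_bg <- spec$n_background_clones
    # satellite clones: a 1-2 mismatch shadow of a dominant clone
    sat_of <- integer(0)
    if (length(dom) && spec$near_duplicate_rate > 0) {
      sat_of <- which(stats::runif(length(dom)) < spec$near_duplicate_rate)
    }
    g <- stats::rgamma(n_bg, shape = spec$background_concentration)
    bg <- g / sum(g) * (1 - sum(dom))

    dom_adj <- dom
    sat_frac <- numeric(0)
    if (length(sat_of)) {
      sat_frac <- 0.1 * dom[sat_of]
      dom_adj[sat_of] <- 0.9 * dom[sat_of]
    }
    seqs <- .random_sequences(length(dom) + n_bg, spec$sequence_length)
    dom_seqs <- seqs[seq_along(dom)]
    bg_seqs <- seqs[length(dom) + seq_len(n_bg)]
    sat_seqs <- vapply(sat_of, function(i) {
      .mutate_sequence(dom_seqs[i], sample(1:2, 1))
    }, character(1))

    probs <- c(dom_adj, sat_frac, bg)
    all_seqs <- c(dom_seqs, sat_seqs, bg_seqs)
    counts <- as.numeric(stats::rmultinom(1, spec$total_reads, probs))
    keep <- counts > 0
    tbl <- clonotype_table(all_seqs[keep], counts[keep],
                           sample_id = sample_id, target = target,
                           total_reads = spec$total_reads)
    truth <- if (spec$phenotype %in% c("monoclonal", "biclonal")) {
      "CLONAL"
    } else {
      "POLYCLONAL"
    }
    list(table = tbl, truth = truth)
  })
}

# deterministic per-case/target sub-seed below 2^31
.derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + j * 1299709) %% 2147483647)
}

#' Generate a labelled synthetic cohort
#'
#' Emits `n_per_phenotype` cases for each requested phenotype, each with one
#' clonotype table per assay target of the lineage, plus a gold label
#' (`CLONAL` for monoclonal/biclonal phenotypes, `POLYCLONAL` otherwise).
#' Per-case parameters are jittered deterministically under `seed`: dominant
#' fractions uniform over `dominant_range` (biclonal cases split that
#' fraction 60/40), background clone counts within +/-10% of the base
#' spec's, total reads within +/-20%. Low-read cases are not jittered above
#' the acceptance gate.
#'
#' @param n_per_phenotype cases per phenotype (>= 1).
#' @param phenotypes character vector of phenotypes to generate.
#' @param lineage `"B"` (IGH FR1/FR2/FR3 + IGK) or `"T"` (TRG + TRB).
#' @param seed master seed for the cohort.
#' @param dominant_range range of the (total) dominant fraction for
#'   monoclonal/biclonal cases.
#' @param base_spec a [synthetic_spec()] supplying background size, reads,
#'   concentration, satellite rate and sequence length.
#' @return an object of class `synthetic_cohort`: list of cases, each a
#'   list with `case_id`, `lineage`, `label`, `phenotype` and `tables`
#'   (named by target); the gold-label data frame is available through
#'   [cohort_labels()].
#' @export
generate_cohort <- function(n_per_phenotype,
                            phenotypes = c("monoclonal", "polyclonal"),
                            lineage = c("T", "B"),
                            seed = 1L,
                            dominant_range = c(0.30, 0.60),
                            base_spec = synthetic_spec("polyclonal")) {
  stopifnot(n_per_phenotype >= 1)
  lineage <- match.arg(lineage)
  targets <- if (lineage == "B") B_TARGETS else T_TARGETS
  cases <- list()
  k <- 0L
  for (ph in phenotypes) {
    for (i in seq_len(n_per_phenotype)) {
      k <- k + 1L
      case_id <- sprintf("%s_%s_%03d", lineage, ph, i)
      jit <- .with_seed(.derive_seed(seed, k), list(
        dom_total = stats::runif(1, dominant_range[1], dominant_range[2]),
        n_bg = round(base_spec$n_background_clones *
                       stats::runif(1, 0.9, 1.1)),
        reads = round(base_spec$total_reads * stats::runif(1, 0.8, 1.2))
      ))
      dom <- switch(ph,
        monoclonal = jit$dom_total,
        biclonal = jit$dom_total * c(0.6, 0.4),
        NULL)
      tables <- list()
      for (j in seq_along(targets)) {
        sp <- synthetic_spec(
          phenotype = ph,
          n_background_clones = if (ph == "restricted") NULL else max(jit$n_bg, 10L),
          dominant_fractions = dom,
          total_reads = if (ph == "low_reads") NULL else jit$reads,
          background_concentration = if (ph == "restricted") NULL else
            base_spec$background_concentration,
          near_duplicate_rate = base_spec$near_duplicate_rate,
          sequence_length = base_spec$sequence_length,
          seed = .derive_seed(seed, k, j)
        )
        tables[[targets[j]]] <- generate_sample(sp, case_id, targets[j])$table
      }
      cases[[case_id]] <- list(
        case_id = case_id,
        lineage = lineage,
        phenotype = ph,
        label = if (ph %in% c("monoclonal", "biclonal")) "CLONAL" else "POLYCLONAL",
        tables = tables
      )
    }
  }
  structure(cases, class = "synthetic_cohort")
}

#' Gold labels of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return a data frame with columns case_id, lineage, label, excluded.
#' @export
cohort_labels <- function(cohort) {
  df <- data.frame(
    case_id = vapply(cohort, `[[`, character(1), "case_id"),
    lineage = vapply(cohort, `[[`, character(1), "lineage"),
    label = vapply(cohort, `[[`, character(1), "label"),
    excluded = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("gold_labels", class(df))
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes one clonotype TSV per case/target plus `manifest.tsv`
#' (case_id, target, table_path) and `labels.tsv`, the inputs expected by
#' the pipeline driver and the evaluation module.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (case in cohort) {
    for (target in names(case$tables)) {
      path <- file.path(dir, sprintf("%s_%s.tsv", case$case_id, target))
      write_clonotype_table(case$tables[[target]], path)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$case_id, target = target, table_path = basename(path),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels <- cohort_labels(cohort)
  utils::write.table(as.data.frame(labels), file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
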