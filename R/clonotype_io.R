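#' Assay targets recognised by the package
#'
#' B-cell lineage targets are the three IGH framework assays plus IGK;
#' T-cell lineage targets are TRG and TRB.
#' @name assay-targets
#' @keywords internal
NULL

ASSAY_TARGETS <- c("IGH_FR1", "IGH_FR2", "IGH_FR3", "IGK", "TRG", "TRB")
B_TARGETS <- c("IGH_FR1", "IGH_FR2", "IGH_FR3", "IGK")
T_TARGETS <- c("TRG", "TRB")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lineage of an assay target
#'
#' @param target one of `IGH_FR1`, `IGH_FR2`, `IGH_FR3`, `IGK`, `TRG`, `TRB`.
#' @return `"B"` or `"T"`.
#' @export
target_lineage <- function(target) {
  target <- match.arg(target, ASSAY_TARGETS)
  if (target %in% B_TARGETS) "B" else "T"
}

#' Construct a clonotype frequency table
#'
#' A clonotype table is one assay's ranked list of unique rearranged V-J
#' nucleotide sequences with their read counts, as produced by amplicon
#' repertoire analysis software. Records are stored sorted by read count
#' (descending), ranks are reassigned 1..N, and `pct_total` is always
#' recomputed as `100 * read_count / total_reads`. Ties on read count are
#' broken by `merged_member_count` (descending) then by sequence
#' (lexicographic, C locale) so output is deterministic across platforms.
#'
#' `total_reads` is the sequencing denominator: tables may list only the top
#' clones, so a supplied `total_reads` larger than the column sum is
#' authoritative. A supplied value smaller than the column sum is ignored
#' (with a warning) in favour of the column sum.
#'
#' @param sequence character vector of nucleotide sequences over `{A,C,G,T,N}`
#'   (lower case accepted, stored upper case).
#' @param read_count non-negative read counts, one per sequence.
#' @param sample_id sample identifier.
#' @param target assay target, or `NA` if unknown.
#' @param total_reads total sequencing reads for the sample/assay; defaults to
#'   `sum(read_count)`.
#' @param v_label,j_label optional V/J gene labels.
#' @param merged_member_count number of raw clonotypes merged into each
#'   record (1 if unmerged).
#' @return an object of class `clonotype_table`: a list with elements
#'   `sample_id`, `target`, `total_reads` and `records` (a data frame with
#'   columns rank, sequence, read_count, pct_total, v_label, j_label,
#'   merged_member_count).
#' @examples
#' tb <- clonotype_table(c("ACGT", "TTTT", "GGGG"), c(30, 50, 20))
#' tb$records$pct_total  # 50, 30, 20
#' @export
clonotype_table <- function(sequence, read_count, sample_id = "", target = NA_character_,
                            total_reads = NULL, v_label = NULL, j_label = NULL,
                            merged_member_count = NULL) {
  n <- length(sequence)
  if (length(read_count) != n) {
    stop("`sequence` and `read_count` must have the same length")
  }
  if (!is.na(target)) target <- match.arg(target, ASSAY_TARGETS)
  sequence <- toupper(as.character(sequence))
  if (n > 0 && any(!grepl("^[ACGTN]+$", sequence))) {
    bad <- which(!grepl("^[ACGTN]+$", sequence))[1]
    stop(sprintf("sequence %d is not a non-empty string over {A,C,G,T,N}", bad))
  }
  read_count <- as.numeric(read_count)
  if (any(is.na(read_count)) || any(read_count < 0)) {
    stop("read counts must be non-negative numbers")
  }
  records <- data.frame(
    rank = integer(n),
    sequence = sequence,
    read_count = read_count,
    pct_total = numeric(n),
    v_label = as.character(v_label %||% rep(NA_character_, n)),
    j_label = as.character(j_label %||% rep(NA_character_, n)),
    merged_member_count = as.integer(merged_member_count %||% rep(1L, n)),
    stringsAsFactors = FALSE
  )
  tbl <- structure(
    list(sample_id = as.character(sample_id), target = target,
         total_reads = total_reads, records = records),
    class = "clonotype_table"
  )
  normalize_clonotype_table(tbl)
}

#' Normalize a clonotype table
#'
#' Sorts records by read count (descending; ties by merged_member_count
#' descending then sequence), reassigns ranks 1..N, resolves `total_reads`
#' against the column sum, and recomputes `pct_total`. Idempotent.
#'
#' @param tbl a `clonotype_table`.
#' @return the normalized `clonotype_table`.
#' @export
normalize_clonotype_table <- function(tbl) {
  stopifnot(inherits(tbl, "clonotype_table"))
  rec <- tbl$records
  if (nrow(rec) > 0) {
    ord <- order(-rec$read_count, -rec$merged_member_count, rec$sequence,
                 method = "radix")
    rec <- rec[ord, , drop = FALSE]
  }
  col_sum <- sum(rec$read_count)
  total <- tbl$total_reads
  if (is.null(total) || is.na(total)) {
    total <- col_sum
  } else if (total < col_sum) {
    warning(sprintf(
      "total_reads (%s) is below the read-count column sum (%s); using the column sum",
      format(total), format(col_sum)))
    total <- col_sum
  }
  rec$rank <- seq_len(nrow(rec))
  rec$pct_total <- if (total > 0) 100 * rec$read_count / total else rep(0, nrow(rec))
  rownames(rec) <- NULL
  tbl$records <- rec
  tbl$total_reads <- as.numeric(total)
  tbl
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> sample=%s target=%s total_reads=%s clones=%d\n",
              x$sample_id, x$target, format(x$total_reads, big.mark = ","),
              nrow(x$records)))
  print(utils::head(x$records, 10))
  if (nrow(x$records) > 10) cat(sprintf("... %d more clones\n", nrow(x$records) - 10))
  invisible(x)
}

# header alias resolution: lower-case, strip everything but letters and '%'
.norm_header <- function(x) gsub("[^a-z%]", "", tolower(x))

.COLUMN_ALIASES <- list(
  rank = c("rank"),
  sequence = c("sequence", "nucleotidesequence", "seq"),
  read_count = c("readcount", "reads", "count", "nreads", "readcounts"),
  pct_total = c("pcttotal", "%totalreads", "percenttotal", "pct", "percent",
                "%reads", "%total", "percentoftotalreads"),
  v_label = c("vlabel", "vgene", "v"),
  j_label = c("jlabel", "jgene", "j"),
  merged_member_count = c("mergedmembercount", "mergedreads", "members", "nmerged")
)

#' Read a clonotype frequency table
#'
#' Reads the tab-separated clonotype tables emitted by amplicon repertoire
#' analysis software. The file may start with a commented sidecar preamble of
#' `#key=value` lines carrying `sample_id`, `target` and `total_reads`.
#' Column headers are matched case-insensitively against a set of common
#' aliases (e.g. "Reads", "Read Count", "% total reads"); unknown columns are
#' ignored. A percent column, when present, is ignored on input: `pct_total`
#' is always recomputed from read counts and the total-read denominator so the
#' table satisfies its own invariants.
#'
#' @param source path to a tab-separated file (UTF-8, LF or CRLF).
#' @param target assay target; overrides any sidecar value.
#' @param sample_id sample identifier; overrides any sidecar value.
#' @param total_reads total-read denominator; overrides any sidecar value.
#'   When absent everywhere it defaults to the read-count column sum.
#' @return a validated, rank-normalized [clonotype_table()].
#' @export
read_clonotype_table <- function(source, target = NULL, sample_id = NULL,
                                 total_reads = NULL) {
  lines <- readLines(source, warn = FALSE)
  lines <- sub("\r$", "", lines)
  n_meta <- 0L
  meta <- list()
  while (n_meta < length(lines) && grepl("^#", lines[n_meta + 1L])) {
    n_meta <- n_meta + 1L
    kv <- sub("^#\\s*", "", lines[n_meta])
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  body <- lines[seq.int(n_meta + 1L, length.out = length(lines) - n_meta)]
  body <- body[nzchar(body) | seq_along(body) == 1L]
  if (length(body) == 0) stop("format error: no header row found in ", source)

  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  norm <- .norm_header(header)
  col_of <- function(field) {
    hits <- which(norm %in% .COLUMN_ALIASES[[field]])
    if (length(hits)) hits[1] else NA_integer_
  }
  seq_col <- col_of("sequence")
  cnt_col <- col_of("read_count")
  if (is.na(seq_col)) stop("format error: missing required column 'sequence'")
  if (is.na(cnt_col)) stop("format error: missing required column 'read_count'")

  data_lines <- body[-1]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  get <- function(col) {
    if (is.na(col)) return(rep(NA_character_, length(fields)))
    vapply(fields, function(f) if (col <= length(f)) f[col] else NA_character_,
           character(1))
  }
  raw_cnt <- get(cnt_col)
  cnt <- suppressWarnings(as.numeric(raw_cnt))
  bad <- which(is.na(cnt) & !is.na(raw_cnt) & nzchar(raw_cnt))
  if (length(bad)) {
    stop(sprintf("parse error: non-numeric read count '%s' at line %d of %s",
                 raw_cnt[bad[1]], n_meta + 1L + bad[1], as.character(source)))
  }
  mm <- suppressWarnings(as.integer(get(col_of("merged_member_count"))))
  mm[is.na(mm)] <- 1L
  vl <- get(col_of("v_label")); vl[!nzchar(vl) | is.na(vl)] <- NA_character_
  jl <- get(col_of("j_label")); jl[!nzchar(jl) | is.na(jl)] <- NA_character_

  if (!is.null(meta[["target"]]) && !nzchar(meta[["target"]])) {
    meta[["target"]] <- NULL
  }
  sidecar_total <- suppressWarnings(as.numeric(meta[["total_reads"]]))
  clonotype_table(
    sequence = get(seq_col),
    read_count = cnt,
    sample_id = sample_id %||% meta[["sample_id"]] %||% "",
    target = target %||% meta[["target"]] %||% NA_character_,
    total_reads = total_reads %||%
      (if (length(sidecar_total) && !is.na(sidecar_total)) sidecar_total else NULL),
    v_label = vl, j_label = jl, merged_member_count = mm
  )
}

#' Write a clonotype frequency table
#'
#' Writes a tab-separated file with a `#key=value` sidecar preamble
#' (sample_id, target, total_reads) and fixed column order (rank, sequence,
#' read_count, pct_total, v_label, j_label, merged_member_count). Percent
#' values are printed with enough significant digits that a write/read round
#' trip preserves the table exactly.
#'
#' @param tbl a [clonotype_table()].
#' @param dest output path or connection.
#' @return invisibly, `dest`.
#' @export
write_clonotype_table <- function(tbl, dest) {
  stopifnot(inherits(tbl, "clonotype_table"))
  rec <- tbl$records
  na_blank <- function(x) ifelse(is.na(x), "", x)
  pre <- c(
    sprintf("#sample_id=%s", tbl$sample_id),
    sprintf("#target=%s", ifelse(is.na(tbl$target), "", tbl$target)),
    sprintf("#total_reads=%s", format(tbl$total_reads, scientific = FALSE))
  )
  header <- paste(c("rank", "sequence", "read_count", "pct_total",
                    "v_label", "j_label", "merged_member_count"), collapse = "\t")
  rows <- if (nrow(rec) == 0) character(0) else {
    paste(rec$rank, rec$sequence,
          format(rec$read_count, scientific = FALSE, trim = TRUE),
          sprintf("%.10g", rec$pct_total),
          na_blank(rec$v_label), na_blank(rec$j_label),
          rec$merged_member_count, sep = "\t")
  }
  writeLines(c(pre, header, rows), dest)
  invisible(dest)
}
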