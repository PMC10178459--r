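# Independent oracles: straight-line reimplementations used only in tests.

# full Wagner-Fischer edit distance, no early exit
dp_edit_distance <- function(a, b) {
  A <- strsplit(chartr("N", "X", a), "", fixed = TRUE)[[1]]
  B <- strsplit(chartr("N", "Z", b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (A[i] == B[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# pairwise distance matrix for the brute-force merge oracle (coded apart
# from the package's vectorised helper)
oracle_dist_matrix <- function(seqs, policy) {
  n <- length(seqs)
  a <- chartr("N", "X", seqs)
  b <- chartr("N", "Z", seqs)
  D <- matrix(Inf, n, n)
  if (policy$length_mode == "bounded_edit") {
    D[] <- utils::adist(a, b)
  } else {
    lens <- nchar(seqs)
    split_a <- strsplit(a, "", fixed = TRUE)
    split_b <- strsplit(b, "", fixed = TRUE)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (lens[i] == lens[j]) D[i, j] <- sum(split_a[[i]] != split_b[[j]])
      }
    }
  }
  D
}

# brute-force greedy merge over an explicit all-pairs distance matrix;
# returns the merged table's (sequence, read_count, merged_member_count)
# sorted the same way the package sorts
brute_merge <- function(tbl, policy) {
  rec <- tbl$records
  n <- nrow(rec)
  if (n < 2) return(rec[, c("sequence", "read_count", "merged_member_count")])
  D <- oracle_dist_matrix(rec$sequence, policy)
  owner <- seq_len(n)  # which record each row ends up in
  for (i in seq_len(min(policy$top_n, n))) {
    if (owner[i] != i) next   # already absorbed, cannot absorb
    for (j in seq_len(min(policy$pool_n, n))) {
      if (j <= i) next
      if (owner[j] != j) next
      if (D[i, j] <= policy$max_mismatch) owner[j] <- i
    }
  }
  keep <- which(owner == seq_len(n))
  out <- data.frame(
    sequence = rec$sequence[keep],
    read_count = vapply(keep, function(i) sum(rec$read_count[owner == i]),
                        numeric(1)),
    merged_member_count = vapply(keep, function(i) {
      sum(rec$merged_member_count[owner == i])
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$read_count, -out$merged_member_count, out$sequence,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- straight-line rule-set oracles (plain percent arithmetic) -------------

.oracle_pcts <- function(tbl) tbl$records$pct_total

oracle_roswell <- function(tbl) {
  p <- .oracle_pcts(tbl)
  total <- tbl$total_reads
  target <- tbl$target
  is_b <- target %in% c("IGH_FR1", "IGH_FR2", "IGH_FR3", "IGK")
  at <- function(r) if (r <= length(p)) p[r] else 0
  if (total < 20000) return("INVALID")
  top2 <- at(1) + at(2)
  bypass <- if (is_b) 30 else 50
  if (top2 >= bypass) return("CLONAL")
  cmax <- if (target %in% c("IGH_FR1", "IGH_FR2", "IGH_FR3")) 1.0 else 1.25
  idx <- 3:10
  idx <- idx[idx <= length(p)]
  qual <- p[idx][p[idx] <= cmax]
  if (length(qual) < 3) return("NEC")
  bkg <- stats::median(qual)
  if (!(top2 >= 10 * bkg)) return("NEC")
  thr <- if (target %in% c("IGH_FR1", "IGH_FR2", "IGH_FR3")) 2.5 else 5
  if (top2 >= thr) "CLONAL" else "NEC"
}

oracle_invivoscribe <- function(tbl) {
  p <- .oracle_pcts(tbl)
  total <- tbl$total_reads
  at <- function(r) if (r <= length(p)) p[r] else 0
  if (total < 20000) return("INVALID")
  p3 <- at(3)
  if ((at(1) > 0 && at(1) >= 2.5 && at(1) >= 10 * p3) ||
      (at(2) > 0 && at(2) >= 2.5 && at(2) >= 10 * p3)) "CLONAL" else "NEC"
}

oracle_msk <- function(tbl) {
  p <- .oracle_pcts(tbl)
  total <- tbl$total_reads
  at <- function(r) if (r <= length(p)) p[r] else 0
  if (total < 30000) return("INVALID")
  if (total >= 100000) { thr <- 2.5; ratio <- 10 } else { thr <- 5; ratio <- 20 }
  # count the dominant leading block
  k <- 0
  for (i in seq_along(p)) {
    if (p[i] >= thr && p[i] >= ratio * at(i + 1)) k <- i
  }
  if (k >= 3 && total > 100000) return("OLIGOCLONAL")
  p3 <- at(3)
  if ((at(1) > 0 && at(1) >= thr && at(1) >= ratio * p3) ||
      (at(2) > 0 && at(2) >= thr && at(2) >= ratio * p3)) "CLONAL" else "NEC"
}

oracle_ns <- function(tbl, min_reads = 1000) {
  p <- .oracle_pcts(tbl)
  total <- tbl$total_reads
  if (total < min_reads) return("INVALID")
  if (length(p) == 0) return("NEC")
  bkg <- NA_real_
  for (r in 2:min(10, max(2, length(p)))) {
    if (r <= length(p) && p[r] <= 0.5 * p[r - 1]) { bkg <- p[r]; break }
  }
  at <- function(r) if (r <= length(p)) p[r] else 0
  if (!is.na(bkg)) {
    if ((at(1) >= 4 && at(1) >= 4.5 * bkg) ||
        (at(2) >= 4 && at(2) >= 4.5 * bkg)) return("CLONAL")
  }
  if (all(p <= 2)) return("NEC")
  "POLYCLONAL_MINOR"
}

oracle_call <- function(tbl, model) {
  switch(model,
    roswell_park = oracle_roswell(tbl),
    invivoscribe = oracle_invivoscribe(tbl),
    msk = oracle_msk(tbl),
    nollet_schumaker = oracle_ns(tbl, 1000),
    ns_modified = oracle_ns(tbl, 20000)
  )
}

MODEL_NAMES <- c("roswell_park", "invivoscribe", "msk",
                 "nollet_schumaker", "ns_modified")
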