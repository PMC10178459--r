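# table-building helpers shared across test files

rand_seqs <- function(n, len = 30) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  out <- apply(m, 1, paste, collapse = "")
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))
    out[d] <- rand_seqs(length(d), len)
  }
  out
}

make_tbl <- function(counts, total = sum(counts), target = "TRG",
                     seqs = NULL, sample_id = "S", len = 30) {
  if (is.null(seqs)) seqs <- rand_seqs(length(counts), len)
  clonotype_table(seqs, counts, sample_id = sample_id, target = target,
                  total_reads = total)
}

# build a table whose listed clones sit at exact percent values of `total`
pct_tbl <- function(pcts, total, target = "TRG", sample_id = "S") {
  counts <- pcts / 100 * total
  stopifnot(max(abs(counts - round(counts))) < 1e-6)
  make_tbl(round(counts), total = total, target = target, sample_id = sample_id)
}

# a total that cannot hit any model percent boundary exactly:
# odd and not divisible by 5 => thresholds 1, 1.25, 2, 2.5, 4, 5, 30, 50
# (all of form p/q with q in {2,4,25,40,50,80,100,10}) are unreachable
boundary_safe_total <- function(x) {
  t <- floor(x)
  if (t %% 2 == 0) t <- t + 1
  while (t %% 5 == 0) t <- t + 2
  t
}

# random table for calling-model fuzz: counts well spread, denominator safe
fuzz_call_table <- function(target = NULL, n_max = 30) {
  if (is.null(target)) target <- sample(c("IGH_FR1", "IGH_FR2", "IGH_FR3",
                                          "IGK", "TRG", "TRB"), 1)
  n <- sample(1:n_max, 1)
  counts <- sample(1:200000, n)
  slack <- sample(0:sum(counts), 1)
  total <- boundary_safe_total(sum(counts) + slack)
  make_tbl(counts, total = total, target = target)
}

# random table for merge fuzz: sequences drawn as mutated copies of a small
# base set so that near-duplicates are common
fuzz_merge_table <- function(n_max = 30, len_max = 40) {
  n <- sample(2:n_max, 1)
  n_base <- max(2, ceiling(n / 3))
  len <- sample(8:len_max, 1)
  base <- rand_seqs(n_base, len)
  seqs <- character(n)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in seq_len(n)) {
    s <- base[sample(n_base, 1)]
    k <- sample(0:5, 1)
    if (k > 0) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in sample(length(ch), min(k, length(ch)))) {
        ch[p] <- sample(alphabet, 1)
      }
      # occasional length change to exercise the edit-distance mode
      if (stats::runif(1) < 0.2) ch <- ch[-sample(length(ch), 1)]
      s <- paste(ch, collapse = "")
    }
    seqs[i] <- s
  }
  dup <- duplicated(seqs)
  seqs[dup] <- rand_seqs(sum(dup), len)
  counts <- sample(1:100000, n)
  make_tbl(counts, total = sum(counts), seqs = seqs)
}
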