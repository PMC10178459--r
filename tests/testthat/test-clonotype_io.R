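test_that("percent and total-read normalization follow the read counts", {
  tb <- clonotype_table(c("ACGTA", "TTTTT", "GGGGG"), c(50, 30, 20))
  expect_equal(tb$total_reads, 100)
  expect_equal(tb$records$pct_total, c(50, 30, 20))
  expect_equal(tb$records$rank, 1:3)

  # unsorted input is re-sorted descending with ranks reassigned
  tb2 <- clonotype_table(c("AAAAA", "CCCCC", "GGGGG"), c(10, 90, 40))
  expect_equal(tb2$records$read_count, c(90, 40, 10))
  expect_equal(tb2$records$sequence, c("CCCCC", "GGGGG", "AAAAA"))
  expect_equal(tb2$records$rank, 1:3)

  # a sidecar total above the column sum is the authoritative denominator
  tb3 <- clonotype_table(c("AAAAA", "CCCCC"), c(30, 20), total_reads = 1000)
  expect_equal(tb3$records$pct_total, c(3, 2))
  # a total below the column sum is replaced by the column sum
  expect_warning(
    tb4 <- clonotype_table(c("AAAAA", "CCCCC"), c(30, 20), total_reads = 10),
    "column sum")
  expect_equal(tb4$total_reads, 50)
})

test_that("rank ties break by member count then sequence, deterministically", {
  tb <- clonotype_table(c("TTTTT", "AAAAA", "CCCCC"), c(10, 10, 10),
                        merged_member_count = c(1L, 1L, 4L))
  expect_equal(tb$records$sequence, c("CCCCC", "AAAAA", "TTTTT"))
})

test_that("normalization is idempotent", {
  set.seed(42)
  for (i in 1:20) {
    tb <- fuzz_call_table()
    once <- normalize_clonotype_table(tb)
    twice <- normalize_clonotype_table(once)
    expect_identical(once, twice)
  }
})

test_that("write then read round-trips tables exactly", {
  set.seed(7)
  path <- withr::local_tempfile(fileext = ".tsv")
  for (i in 1:20) {
    tb <- fuzz_call_table()
    tb$sample_id <- sprintf("S%02d", i)
    write_clonotype_table(tb, path)
    back <- read_clonotype_table(path)
    expect_identical(back$records$sequence, tb$records$sequence)
    expect_equal(back$records$read_count, tb$records$read_count)
    expect_equal(back$records$rank, tb$records$rank)
    expect_equal(back$total_reads, tb$total_reads)
    expect_equal(back$records$pct_total, tb$records$pct_total, tolerance = 1e-9)
    expect_identical(back$sample_id, tb$sample_id)
    expect_identical(back$target, tb$target)
  }

  # N bases and labels survive verbatim; empty table gives a header-only body
  tb <- clonotype_table(c("ACGNN", "TTTTT"), c(6, 4),
                        v_label = c("IGHV1-2", NA), j_label = c(NA, "IGHJ4"))
  write_clonotype_table(tb, path)
  back <- read_clonotype_table(path)
  expect_identical(back$records$sequence, c("ACGNN", "TTTTT"))
  expect_identical(back$records$v_label, c("IGHV1-2", NA))
  expect_identical(back$records$j_label, c(NA, "IGHJ4"))

  empty <- clonotype_table(character(0), numeric(0), total_reads = 0)
  write_clonotype_table(empty, path)
  back <- read_clonotype_table(path)
  expect_equal(nrow(back$records), 0)
})

test_that("header aliases are accepted and errors name the problem", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Rank\tSequence\tRead Count\t% total reads",
               "1\tACGTACGT\t50\t50.0",
               "2\tTTTTACGT\t30\t30.0",
               "3\tGGGGACGT\t20\t20.0"), path)
  tb <- read_clonotype_table(path, target = "IGH_FR1")
  expect_equal(tb$records$read_count, c(50, 30, 20))
  expect_equal(tb$records$pct_total, c(50, 30, 20))
  expect_identical(tb$target, "IGH_FR1")

  # percent column absent: recomputed from counts
  writeLines(c("sequence\treads", "ACGTACGT\t75", "TTTTACGT\t25"), path)
  expect_equal(read_clonotype_table(path)$records$pct_total, c(75, 25))

  # an inconsistent percent column is ignored in favour of the counts
  writeLines(c("sequence\treads\tpct", "ACGTACGT\t75\t10", "TTTTACGT\t25\t90"),
             path)
  expect_equal(read_clonotype_table(path)$records$pct_total, c(75, 25))

  writeLines(c("sequence\tsomething", "ACGT\t5"), path)
  expect_error(read_clonotype_table(path), "read_count")
  writeLines(c("reads\tfoo", "5\tx"), path)
  expect_error(read_clonotype_table(path), "sequence")
  writeLines(c("sequence\treads", "ACGT\t5", "TTTT\tabc"), path)
  expect_error(read_clonotype_table(path), "line 3")
})

test_that("sidecar metadata is parsed and explicit arguments win", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#sample_id=P01", "#target=TRG", "#total_reads=200",
               "sequence\treads", "ACGTACGT\t60", "TTTTACGT\t40"), path)
  tb <- read_clonotype_table(path)
  expect_identical(tb$sample_id, "P01")
  expect_identical(tb$target, "TRG")
  expect_equal(tb$total_reads, 200)
  expect_equal(tb$records$pct_total, c(30, 20))
  tb2 <- read_clonotype_table(path, target = "TRB", total_reads = 400)
  expect_identical(tb2$target, "TRB")
  expect_equal(tb2$records$pct_total, c(15, 10))
})
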