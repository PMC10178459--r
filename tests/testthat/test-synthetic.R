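test_that("generation is deterministic under a seed and conserves reads", {
  sp <- synthetic_spec("biclonal", seed = 42, near_duplicate_rate = 1)
  a <- generate_sample(sp, "S1", "IGK")
  b <- generate_sample(sp, "S1", "IGK")
  expect_identical(a, b)
  expect_equal(sum(a$table$records$read_count), sp$total_reads)
  expect_identical(a$truth, "CLONAL")
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_sample(sp)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("dominant clones land near their target fractions", {
  sp <- synthetic_spec("monoclonal", dominant_fractions = 0.40,
                       total_reads = 200000, n_background_clones = 500,
                       seed = 9)
  tb <- generate_sample(sp, "S", "TRG")$table
  # multinomial standard error ~ 0.11 percentage points at n = 200,000
  expect_lt(abs(tb$records$pct_total[1] - 40), 1.0)
})

test_that("spec validation rejects infeasible phenotypes", {
  expect_error(synthetic_spec("monoclonal", dominant_fractions = c(0.4, 0.3)),
               "exactly 1")
  expect_error(synthetic_spec("biclonal", dominant_fractions = c(0.7, 0.4)),
               "less than 1")
  expect_error(synthetic_spec("restricted", n_background_clones = 50), "<= 12")
  expect_error(synthetic_spec("polyclonal", dominant_fractions = 0.4))
})

test_that("satellite clones sit within merge range of their dominant clone", {
  sp <- synthetic_spec("monoclonal", near_duplicate_rate = 1, seed = 77)
  tb <- generate_sample(sp, "S", "TRB")$table
  merged <- merge_top_clones(tb, merge_policy())
  # the satellite is absorbed: the top clone gains a member
  expect_gte(merged$records$merged_member_count[1], 2L)
  expect_lt(nrow(merged$records), nrow(tb$records))
})

test_that("phenotype defaults express their intended repertoire shape", {
  poly <- generate_sample(synthetic_spec("polyclonal", seed = 3))$table
  expect_gte(nrow(poly$records), 400)
  expect_lt(max(poly$records$pct_total), 1)

  restr <- generate_sample(synthetic_spec("restricted", seed = 3))$table
  expect_lte(nrow(restr$records), 12)
  expect_gt(min(restr$records$pct_total), 1.25)

  low <- generate_sample(synthetic_spec("low_reads", seed = 3))$table
  expect_lt(low$total_reads, 20000)
})

test_that("cohorts are labelled, complete, and reproducible", {
  co <- generate_cohort(1, c("polyclonal", "monoclonal"), lineage = "T",
                        seed = 5)
  expect_length(co, 2)
  expect_equal(sum(vapply(co, function(x) length(x$tables), integer(1))), 4)
  lab <- cohort_labels(co)
  expect_setequal(lab$label, c("POLYCLONAL", "CLONAL"))
  co2 <- generate_cohort(1, c("polyclonal", "monoclonal"), lineage = "T",
                         seed = 5)
  expect_identical(co, co2)

  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_equal(nrow(manifest), 4)
  back <- read_clonotype_table(file.path(dir, manifest$table_path[1]))
  want <- co[[manifest$case_id[1]]]$tables[[manifest$target[1]]]
  expect_equal(back$records$read_count, want$records$read_count)
})

test_that("flat polyclonal samples are never called clonal by any model", {
  for (seed in 1:25) {
    tb <- generate_sample(synthetic_spec("polyclonal", seed = seed),
                          "S", "TRG")$table
    merged <- merge_top_clones(tb, merge_policy())
    for (model in MODEL_NAMES) {
      expect_false(call_clonality(merged, model_config(model))$call
                   %in% c("CLONAL", "OLIGOCLONAL"),
                   info = sprintf("model %s seed %d", model, seed))
    }
  }
})

test_that("dominant clones at modest fractions are detected by the decision tree", {
  for (seed in 1:25) {
    sp <- synthetic_spec("monoclonal", dominant_fractions = 0.10, seed = seed)
    tb <- generate_sample(sp, "S", "TRG")$table
    merged <- merge_top_clones(tb, merge_policy())
    expect_identical(call_clonality(merged, model_config("roswell_park"))$call,
                     "CLONAL", info = paste("seed", seed))
  }
})
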