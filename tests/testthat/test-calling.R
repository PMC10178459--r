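test_that("the decision-tree polyclonal background is the median of qualifying clones", {
  # ranks 3..10 at 0.9..0.2 percent, ceiling 1: all 8 qualify, median 0.55
  tb <- pct_tbl(c(40, 5, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2), 100000)
  expect_equal(rp_polyclonal_background(tb, 1.0), 0.55)
  # nothing qualifies: undefined
  tb2 <- pct_tbl(c(40, 5, 2, 1.8, 1.5), 100000)
  expect_true(is.na(rp_polyclonal_background(tb2, 1.0)))
  # exactly three qualify, inclusive at the ceiling
  tb3 <- pct_tbl(c(40, 5, 1, 0.5, 0.2), 100000)
  expect_equal(rp_polyclonal_background(tb3, 1.0), 0.5)
  # two qualify: still undefined (at least three required)
  tb4 <- pct_tbl(c(40, 5, 2, 0.5, 0.2), 100000)
  expect_true(is.na(rp_polyclonal_background(tb4, 1.0)))
})

test_that("the first-two-fold-drop background follows the rank scan", {
  tb <- pct_tbl(c(40, 5, 4.8, 0.5), 100000)
  expect_equal(ns_polyclonal_background(tb), 5)      # rank 2 is <= half of 40
  tb2 <- pct_tbl(c(10, 9, 8.5, 8, 7.8, 7.5, 7.2, 7, 6.8, 6.6), 100000)
  expect_true(is.na(ns_polyclonal_background(tb2)))  # no two-fold drop
  tb3 <- pct_tbl(c(40, 39, 10, 0.5), 100000)
  expect_equal(ns_polyclonal_background(tb3), 10)    # first drop at rank 3
})

test_that("every decision-tree fixture yields its expected call and rule", {
  for (fx in decision_fixtures()) {
    got <- call_clonality(fx$tbl, model_config(fx$model))
    expect_identical(got$call, fx$call, info = fx$name)
    expect_identical(got$fired_rule, fx$rule, info = fx$name)
    expect_identical(got$model_name, fx$model, info = fx$name)
  }
})

test_that("fixture calls agree with the straight-line oracle rule sets", {
  for (fx in decision_fixtures()) {
    expect_identical(oracle_call(fx$tbl, fx$model),
                     call_clonality(fx$tbl, model_config(fx$model))$call,
                     info = fx$name)
  }
})

test_that("tables with fewer than three clones are handled by the stated fallbacks", {
  # missing ranks contribute zero percent in the decision tree
  one <- pct_tbl(35, 100000, target = "IGH_FR1")
  expect_identical(call_roswell_b(one)$call, "CLONAL")   # 35 >= 30, step 2
  small <- pct_tbl(c(4, 3), 100000, target = "TRG")
  expect_identical(call_roswell_t(small)$fired_rule, "step3")  # no background
  # rank-3 percent treated as zero: the percent gate alone decides
  iv <- pct_tbl(c(3, 1), 100000)
  expect_identical(call_invivoscribe(iv)$call, "CLONAL")
  # empty table above the read gate is a valid negative
  empty <- clonotype_table(character(0), numeric(0), total_reads = 50000,
                           target = "TRG")
  expect_identical(call_invivoscribe(empty)$call, "NEC")
  expect_identical(call_invivoscribe(empty)$fired_rule, "zero_clones")
  expect_identical(call_msk(empty)$call, "NEC")
  expect_identical(call_nollet_schumaker(empty)$call, "NEC")
})

test_that("fuzzed tables match the straight-line oracles for every model", {
  set.seed(97)
  for (i in 1:200) {
    tb <- fuzz_call_table()
    for (model in MODEL_NAMES) {
      expect_identical(call_clonality(tb, model_config(model))$call,
                       oracle_call(tb, model),
                       info = sprintf("model %s, iteration %d", model, i))
    }
  }
})

test_that("calls are invariant under uniform read-count scaling", {
  set.seed(101)
  for (i in 1:100) {
    tb <- fuzz_call_table()
    k <- sample(2:20, 1)
    scaled <- tb
    scaled$records$read_count <- scaled$records$read_count * k
    scaled$total_reads <- scaled$total_reads * k
    scaled <- normalize_clonotype_table(scaled)
    for (model in MODEL_NAMES) {
      orig <- call_clonality(tb, model_config(model))$call
      if (orig != "INVALID") {
        expect_identical(call_clonality(scaled, model_config(model))$call, orig,
                         info = sprintf("model %s, iteration %d, k=%d", model, i, k))
      }
    }
  }
})

test_that("growing the dominant clone never flips the decision tree to negative", {
  set.seed(103)
  for (i in 1:100) {
    tb <- fuzz_call_table(target = sample(c("IGH_FR1", "IGK", "TRG"), 1))
    before <- call_clonality(tb, model_config("roswell_park"))$call
    if (before != "CLONAL") next
    up <- tb
    m <- sample(2:5, 1)
    extra <- up$records$read_count[1] * (m - 1)
    up$records$read_count[1] <- up$records$read_count[1] * m
    up$total_reads <- up$total_reads + extra
    up <- normalize_clonotype_table(up)
    expect_identical(call_clonality(up, model_config("roswell_park"))$call,
                     "CLONAL", info = paste("iteration", i))
  }
})

test_that("any table clearing the top-two bypass is clonal regardless of background", {
  set.seed(107)
  for (i in 1:100) {
    target <- sample(c("IGH_FR1", "IGK", "TRG"), 1)
    bypass <- if (target == "TRG") 50 else 30
    total <- sample(20000:200000, 1)
    top2 <- min(ceiling(bypass / 100 * total) + sample(0:floor(0.04 * total), 1),
                floor(0.98 * total))
    c1 <- ceiling(top2 * 0.6); c2 <- top2 - c1
    remaining <- total - top2
    bg <- sample(seq_len(max(1, min(c2 - 1, 3000))), sample(3:20, 1),
                 replace = TRUE)                     # arbitrary background shape
    while (sum(bg) > remaining) bg <- floor(bg / 2)
    bg <- bg[bg > 0]
    tb <- make_tbl(c(c1, c2, sort(bg, decreasing = TRUE)), total = total,
                   target = target)
    t2 <- sum(tb$records$read_count[1:2])
    expect_gte(t2 * 100, bypass * tb$total_reads)
    got <- call_clonality(tb, model_config("roswell_park"))
    expect_identical(got$call, "CLONAL", info = paste("iteration", i))
    expect_identical(got$fired_rule, "step2")
  }
})

test_that("case aggregation is clonal if any assay is clonal", {
  mk <- function(target, call) {
    structure(list(sample_id = "C1", target = target, call = call,
                   dominant_pcts = numeric(0), background_pct = NA_real_,
                   fired_rule = "x", model_name = "roswell_park"),
              class = "assay_call")
  }
  res <- aggregate_case(list(mk("IGH_FR1", "NEC"), mk("IGH_FR2", "CLONAL"),
                             mk("IGH_FR3", "NEC"), mk("IGK", "NEC")), "C1")
  expect_identical(res$b_cell_call, "CLONAL")
  expect_true(is.na(res$t_cell_call))

  res2 <- aggregate_case(list(mk("IGH_FR1", "INVALID"), mk("IGH_FR2", "INVALID"),
                              mk("IGH_FR3", "INVALID"), mk("IGK", "INVALID")),
                         "C2")
  expect_identical(res2$b_cell_call, "INVALID")

  res3 <- aggregate_case(list(mk("TRG", "NEC"), mk("TRB", "NEC")), "C3")
  expect_identical(res3$t_cell_call, "NEC")

  # oligoclonal / minor-clonal results are valid negatives at the case level
  res4 <- aggregate_case(list(mk("TRG", "INVALID"), mk("TRB", "POLYCLONAL_MINOR")),
                         "C4")
  expect_identical(res4$t_cell_call, "NEC")
})
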