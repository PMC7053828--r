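# Published per-sequence benchmark counts for the evaluation metrics
# (GS, TP, FP and the expected displayed HR / MR for each row).
benchmark_rows <- list(
  list(name = "T1c",   GS = 33,  TP = 27,  FP = 11, HR = 81.81, MR = 0.65),
  list(name = "T2",    GS = 48,  TP = 44,  FP = 19, HR = 91.66, MR = 0.72),
  list(name = "FSPGR", GS = 49,  TP = 45,  FP = 21, HR = 91.83, MR = 0.70),
  list(name = "Total", GS = 130, TP = 116, FP = 51, HR = 89.23, MR = 0.70)
)

test_that("hit and matching rates reproduce the benchmark table rows", {
  for (row in benchmark_rows) {
    cnt <- eval_counts(GS = row$GS, TP = row$TP, FP = row$FP)
    expect_equal(display_hr(hit_rate(cnt)), row$HR, info = row$name)
    expect_equal(display_mr(matching_rate(cnt)), row$MR, info = row$name)
  }
  # spot check the underlying full-precision values
  expect_equal(hit_rate(eval_counts(130, 116)), 116 / 130 * 100)
  expect_equal(matching_rate(eval_counts(130, 116, 51)), 90.5 / 130)
})

test_that("perfect detection gives HR 100 and the ideal MR of exactly 1", {
  perfect <- eval_counts(GS = 37, TP = 37, FP = 0)
  expect_identical(matching_rate(perfect), 1)
  expect_equal(hit_rate(perfect), 100)
  expect_equal(display_hr(hit_rate(perfect)), 100)
})

test_that("metric invariants hold across count grids", {
  for (gs in c(1, 7, 50)) for (tp in 0:gs) for (fp in c(0, 3, 11)) {
    cnt <- eval_counts(gs, tp, fp)
    hr <- hit_rate(cnt); mr <- matching_rate(cnt)
    expect_lte(mr, hr / 100 + 1e-12)
    if (fp == 0) expect_equal(mr, hr / 100)
    # HR invariant under scaling all counts
    expect_equal(hit_rate(eval_counts(gs * 3, tp * 3, fp * 3)), hr)
  }
  expect_error(hit_rate(eval_counts(0, 0)), "undefined")
  expect_error(matching_rate(eval_counts(0, 0)), "undefined")
  expect_error(eval_counts(5, 6), "exceed")
  expect_error(eval_counts(-1, 0), ">= 0")
})

test_that("dice coefficient counts pixel overlap", {
  a <- matrix(FALSE, 6, 6); a[2:4, 2:4] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[3:5, 3:5] <- TRUE   # 4-pixel intersection
  expect_equal(dice_coefficient(a, b), 2 * 4 / 18)
  expect_equal(dice_coefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_equal(dice_coefficient(a, matrix(FALSE, 6, 6)), 0)
  expect_error(dice_coefficient(a, matrix(TRUE, 3, 3)), "differ")
})

test_that("slice judgement separates TP, FN and spurious components", {
  gold <- matrix(FALSE, 10, 10); gold[3:5, 3:5] <- TRUE

  j <- judge_slice(gold, gold)
  expect_true(j$tp); expect_false(j$fn)
  expect_equal(j$fp_count, 0L); expect_equal(j$overlap, 1)

  j2 <- judge_slice(matrix(FALSE, 10, 10), gold)
  expect_false(j2$tp); expect_true(j2$fn); expect_equal(j2$fp_count, 0L)

  pred <- gold; pred[8:9, 8:9] <- TRUE            # gold plus a spurious blob
  j3 <- judge_slice(pred, gold)
  expect_true(j3$tp); expect_equal(j3$fp_count, 1L)
  expect_equal(j3$overlap, 2 * 9 / (13 + 9))

  # tumor-free slice: every component is a false positive
  j4 <- judge_slice(pred, matrix(FALSE, 10, 10))
  expect_false(j4$tp); expect_false(j4$fn); expect_equal(j4$fp_count, 2L)

  # a component below the overlap threshold does not count as a hit
  tiny <- matrix(FALSE, 10, 10); tiny[3, 3] <- TRUE
  j5 <- judge_slice(tiny, gold, min_overlap = 0.5)
  expect_false(j5$tp); expect_true(j5$fn)
})

test_that("aggregation sums judgements per sequence with display conventions", {
  gold <- matrix(FALSE, 8, 8); gold[3:5, 3:5] <- TRUE
  empty <- matrix(FALSE, 8, 8)
  spur <- empty; spur[7, 7] <- TRUE
  js <- list(
    judge_slice(gold, gold),          # T2 hit
    judge_slice(empty, gold),         # T2 miss
    judge_slice(spur, gold),          # T2 miss + 1 FP
    judge_slice(gold, gold)           # T1c hit
  )
  tab <- aggregate_judgements(js, c("T2", "T2", "T2", "T1c"))
  t2 <- tab[tab$sequence == "T2", ]
  expect_equal(unlist(t2[c("GS", "TP", "FP", "FN")]),
               c(GS = 3, TP = 1, FP = 1, FN = 2))
  expect_equal(t2$HR, display_hr(100 / 3))
  expect_equal(t2$MR, display_mr(0.5 / 3))
  total <- tab[tab$sequence == "Total", ]
  expect_equal(total$GS, 4)
  expect_equal(total$TP, 2)

  single <- aggregate_judgements(list(judge_slice(gold, gold)), "T2")
  expect_equal(single$HR, c(100, 100))
  expect_equal(single$MR, c(1, 1))
})
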