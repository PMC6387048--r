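test_that("identical labelings give a perfect confusion matrix", {
  det <- seg_tbl(c(2, 10), c(4, 12))
  cc <- fuzzy_confusion(det, det, 20, 100)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$tp + cc$tn, 20 * 100)
})

test_that("the literal residual rule forgives 10%..1.5 s overshoots only", {
  fs <- 100
  expert <- seg_tbl(5, 15)              # 10-s artifact
  # 1.2-s overshoot: >= 10% of 10 s and <= 1.5 s -> counted TP
  det <- seg_tbl(5, 16.2, source = "detector")
  cc <- fuzzy_confusion(det, expert, 30, fs)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$tp, round(11.2 * fs))
  # 2.0-s overshoot exceeds the 1.5-s cap -> FP
  det2 <- seg_tbl(5, 17, source = "detector")
  cc2 <- fuzzy_confusion(det2, expert, 30, fs)
  expect_equal(cc2$fp, round(2 * fs))
  # 0.5-s overshoot is under the 10% floor -> FP under the literal rule...
  det3 <- seg_tbl(5, 15.5, source = "detector")
  cc3 <- fuzzy_confusion(det3, expert, 30, fs)
  expect_equal(cc3$fp, round(0.5 * fs))
  # ...but forgiven under the cap rule
  cc4 <- fuzzy_confusion(det3, expert, 30, fs, rule = "cap")
  expect_equal(cc4$fp, 0L)
})

test_that("expert-only residuals at borders are forgiven as TN", {
  fs <- 100
  expert <- seg_tbl(5, 15)
  # detection misses the last 1.2 s of the artifact: lenient -> TN
  det <- seg_tbl(5, 13.8, source = "detector")
  cc <- fuzzy_confusion(det, expert, 30, fs)
  expect_equal(cc$fn, 0L)
  # clean 20 s plus the forgiven 1.2-s residual
  expect_equal(cc$tn, round((30 - 10 + 1.2) * fs))
  # missing 2.0 s exceeds the cap -> FN
  det2 <- seg_tbl(5, 13, source = "detector")
  cc2 <- fuzzy_confusion(det2, expert, 30, fs)
  expect_equal(cc2$fn, round(2 * fs))
})

test_that("disagreements away from any expert border are plain FP/FN", {
  fs <- 100
  expert <- seg_tbl(20, 25)
  det <- seg_tbl(5, 6, source = "detector")  # isolated false detection
  cc <- fuzzy_confusion(det, expert, 40, fs)
  expect_equal(cc$fp, round(1 * fs))
  expect_equal(cc$fn, round(5 * fs))  # whole artifact missed, no adjacency
})

test_that("strict rule equals the plain sample-wise confusion matrix", {
  set.seed(191)
  fs <- 50
  for (rep_i in 1:5) {
    mk <- function() {
      starts <- sort(runif(4, 0, 50))
      ends <- starts + runif(4, 0.5, 3)
      keep <- c(TRUE, diff(starts) > 3.6)
      seg_tbl(starts[keep], ends[keep])
    }
    det <- mk(); exp_ <- mk()
    cc <- fuzzy_confusion(det, exp_, 60, fs, rule = "strict")
    dm <- segments_to_mask(det, 60, fs); em <- segments_to_mask(exp_, 60, fs)
    expect_equal(cc$tp, sum(dm & em))
    expect_equal(cc$fp, sum(dm & !em))
    expect_equal(cc$fn, sum(!dm & em))
    expect_equal(cc$tn, sum(!dm & !em))
  }
})

test_that("enlarging the leniency cap never increases FP + FN", {
  set.seed(201)
  fs <- 50
  expert <- seg_tbl(c(5, 20, 35), c(9, 28, 37))
  det <- seg_tbl(c(4.1, 20.6, 34.2), c(9.8, 29.9, 36.5), source = "detector")
  errs <- vapply(c(0.5, 1.0, 1.5, 2.5), function(cap) {
    cc <- fuzzy_confusion(det, expert, 50, fs, max_lenient_s = cap)
    cc$fp + cc$fn
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("kappa, agreement, Se and FDR follow their closed forms", {
  r1 <- kappa_from_counts(new_confusion_for_test(50, 0, 50, 0))
  expect_equal(r1$kappa, 1)
  expect_equal(r1$agreement, 1)
  r2 <- kappa_from_counts(new_confusion_for_test(25, 25, 25, 25))
  expect_equal(r2$kappa, 0)
  expect_equal(r2$agreement, 0.5)
  r3 <- kappa_from_counts(new_confusion_for_test(80, 20, 880, 20))
  expect_equal(r3$sensitivity, 0.8)
  expect_equal(r3$fdr, 0.2)
  # kappa <= agreement whenever chance agreement is non-negative
  set.seed(211)
  for (rep_i in 1:10) {
    cc <- new_confusion_for_test(sample(100, 1), sample(100, 1),
                                 sample(100, 1), sample(100, 1))
    r <- kappa_from_counts(cc)
    expect_lte(r$kappa, r$agreement + 1e-12)
  }
  # missing-value conventions
  r4 <- kappa_from_counts(new_confusion_for_test(0, 0, 90, 10))
  expect_true(is.na(r4$fdr))
  r5 <- kappa_from_counts(new_confusion_for_test(0, 10, 90, 0))
  expect_true(is.na(r5$sensitivity))
  expect_error(kappa_from_counts(new_confusion_for_test(0, 0, 0, 0)),
               class = "rps_usage_error")
})

test_that("kappa is invariant to swapping TP/TN together with FP/FN", {
  set.seed(221)
  for (rep_i in 1:10) {
    tp <- sample(200, 1); fp <- sample(200, 1)
    tn <- sample(200, 1); fn <- sample(200, 1)
    k1 <- kappa_from_counts(new_confusion_for_test(tp, fp, tn, fn))$kappa
    k2 <- kappa_from_counts(new_confusion_for_test(tn, fn, tp, fp))$kappa
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("segment rasterization round-trips and rejects bad intervals", {
  segs <- seg_tbl(c(1, 5.5), c(2.25, 7))
  m <- segments_to_mask(segs, 10, 100)
  back <- mask_to_segments(m, 100)
  expect_equal(back$start_s, segs$start_s)
  expect_equal(back$end_s, segs$end_s)
  expect_error(segments_to_mask(seg_tbl(5, 4), 10, 100),
               class = "rps_usage_error")
  expect_error(fuzzy_confusion(seg_tbl(c(1, 2), c(3, 4)), seg_tbl(1, 2), 10, 100),
               class = "rps_usage_error")
})
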