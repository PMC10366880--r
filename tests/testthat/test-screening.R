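test_that("pairwise percent difference uses the mean-of-pair denominator", {
  expect_equal(pairwise_pct_diff(100, 100), 0)
  expect_equal(round(pairwise_pct_diff(110, 100), 3), 9.524)
  expect_equal(round(pairwise_pct_diff(2000, 1780), 2), 11.64)
  expect_equal(pairwise_pct_diff(100, 110), pairwise_pct_diff(110, 100))
  expect_error(pairwise_pct_diff(0, 100), "positive")
})

test_that("signed deviation is relative to the reference", {
  expect_equal(signed_deviation(1866, 1866), 0)
  expect_equal(round(signed_deviation(1900, 1866), 1), 1.8)
  expect_equal(round(signed_deviation(1820, 1866), 1), -2.5)
  expect_error(signed_deviation(100, 0), "positive")
})

test_that("screening flags exactly the pairs over threshold", {
  tkvs <- setNames(c(2000, 2000, 2000, 2000, 1780), tkv_sequences())
  scr <- screen_exam(tkvs)
  # brute-force oracle over all 10 pairs
  combs <- combn(names(tkvs), 2)
  expected <- sum(apply(combs, 2, function(p)
    pairwise_pct_diff(tkvs[p[1]], tkvs[p[2]]) > 10))
  expect_equal(nrow(scr$flagged_pairs), expected)
  expect_equal(expected, 4L)
  expect_true(all(scr$flagged_pairs$seq_a == "COR_SSFP" |
                    scr$flagged_pairs$seq_b == "COR_SSFP"))

  even <- setNames(c(2000, 2100, 1950, 2050, 2020), tkv_sequences())
  scr2 <- screen_exam(even)
  expect_equal(nrow(scr2$flagged_pairs), 0L)
  expect_equal(round(max(scr2$matrix), 2), 7.41)

  same <- setNames(rep(2000, 5), tkv_sequences())
  expect_false(screen_exam(same)$review)
  expect_error(screen_exam(c(a = 1000)), "two sequences")
})

test_that("pairwise matrix is symmetric with zero diagonal", {
  tkvs <- setNames(c(1900, 1898, 1834, 1875, 1820), tkv_sequences())
  m <- screen_exam(tkvs)$matrix
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
})

test_that("raising the threshold never flags more pairs", {
  set.seed(42)
  for (i in 1:20) {
    tkvs <- setNames(runif(5, 1000, 2500), tkv_sequences())
    n <- sapply(c(5, 10, 15, 20), function(th)
      nrow(screen_exam(tkvs, screening_config(threshold_pct = th))$flagged_pairs))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("reference TKV averages the unflagged sequences", {
  tkvs <- setNames(c(1900, 1898, 1834, 1875, 1820), tkv_sequences())
  expect_equal(reference_tkv(tkvs)$reference_ml, 1865.4)

  tkvs2 <- setNames(c(2000, 2000, 2000, 2000, 1780), tkv_sequences())
  expect_equal(reference_tkv(tkvs2, "COR_SSFP")$reference_ml, 2000)

  all_bad <- reference_tkv(tkvs2, tkv_sequences())
  expect_true(is.na(all_bad$reference_ml))
  expect_equal(all_bad$status, "MANUAL_REVIEW")
})

test_that("excluding an above-reference sequence lowers the reference", {
  set.seed(7)
  for (i in 1:20) {
    tkvs <- setNames(runif(5, 1000, 2500), tkv_sequences())
    ref_all <- reference_tkv(tkvs)$reference_ml
    hi <- names(which.max(tkvs))
    lo <- names(which.min(tkvs))
    expect_lt(reference_tkv(tkvs, hi)$reference_ml, ref_all)
    expect_gt(reference_tkv(tkvs, lo)$reference_ml, ref_all)
  }
})
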