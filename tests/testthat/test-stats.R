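test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(100, 100, 100)), 0)
  expect_equal(coefficient_of_variation(c(90, 100, 110)), 10)
  expect_equal(round(coefficient_of_variation(c(1893, 1905, 1903)), 3), 0.338)
  expect_true(is.na(coefficient_of_variation(1000)))
})

test_that("observer agreement reports mean, CV and max pairwise difference", {
  a <- observer_agreement(c(1893, 1905, 1903))
  expect_equal(round(a$mean_ml), 1900)
  b <- observer_agreement(c(100, 101, 102))
  expect_equal(round(b$max_pct_diff, 3), 1.980)
  c3 <- observer_agreement(c(1500, 1500, 1500))
  expect_equal(c3$cv_pct, 0)
  expect_equal(c3$max_pct_diff, 0)
})

test_that("Bland-Altman limits are mean +- 1.96 sample SD", {
  ba <- bland_altman(c(-1, 0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(unname(ba$loa), c(-1.96, 1.96))
  ba2 <- bland_altman(c(5, 5, 5, 5))
  expect_equal(ba2$mean_diff, 5)
  expect_equal(unname(ba2$loa), c(5, 5))
  ba3 <- bland_altman(c(10, 12, 9), c(10, 12, 9))
  expect_equal(ba3$mean_diff, 0)
  expect_equal(unname(ba3$loa), c(0, 0))
})

test_that("single-exam deviations from the mean reference balance out", {
  tkvs <- setNames(c(1900, 1898, 1834, 1875, 1820), tkv_sequences())
  ref <- reference_tkv(tkvs)$reference_ml
  dev <- signed_deviation(tkvs, ref)
  # deviations weighted by 1/reference sum to zero for a mean reference
  expect_equal(sum(dev), 0, tolerance = 1e-10)
})

test_that("sequence_bias averages only included exams", {
  dev <- data.frame(
    exam_id = rep(c("e1", "e2"), each = 2),
    sequence = rep(c("AX_T2", "COR_T2"), 2),
    deviation_pct = c(1, 2, 3, 100),
    included = c(TRUE, TRUE, TRUE, FALSE))
  sb <- sequence_bias(dev)
  expect_equal(unname(sb$bias["AX_T2"]), 2)
  expect_equal(unname(sb$bias["COR_T2"]), 2)
  expect_equal(unname(sb$n["COR_T2"]), 1L)
  expect_equal(sum(sb$histogram$count[sb$histogram$sequence == "AX_T2"]), 2L)
})

test_that("pairwise matrices are symmetric and respect exclusions", {
  tkv_pre <- rbind(c(2000, 2000, 2000, 2000, 2000),
                   c(1500, 1500, 1500, 1500, 1800))
  colnames(tkv_pre) <- tkv_sequences()
  inc <- matrix(TRUE, 2, 5, dimnames = list(NULL, tkv_sequences()))
  inc[2, 5] <- FALSE   # exclude the outlying COR_SSFP in exam 2
  pm <- pairwise_matrix(tkv_pre, tkv_pre, inc)
  expect_equal(pm$pre, t(pm$pre))
  expect_equal(unname(diag(pm$pre)), rep(0, 5))
  expect_true(all(pm$pre[1:4, 1:4] == 0))
  expect_gt(pm$pre["AX_T2", "COR_SSFP"], 0)
  expect_equal(pm$post["AX_T2", "COR_SSFP"], 0)  # only exam 1 contributes
})
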