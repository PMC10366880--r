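test_that("volume formula follows voxel count x pixel area x slice spacing", {
  mask <- array(0L, c(10, 10, 10))
  mask[1:10, 1:10, 1:10] <- 1L
  st <- slice_stack(mask, positions_mm = 0:9, pixel_spacing_mm = c(1, 1),
                    nominal_spacing_mm = 1, orientation = "axial",
                    sequence = "AX_T2")
  expect_equal(tkv(st)$total_ml, 1.000)

  empty <- slice_stack(array(0L, c(5, 5, 5)), positions_mm = 0:4,
                       pixel_spacing_mm = c(1, 1), nominal_spacing_mm = 1,
                       orientation = "axial", sequence = "AX_T2")
  # both the labeling and the volume step warn about the empty mask
  expect_warning(expect_warning(v <- tkv(empty), "empty"), "empty")
  expect_equal(v$total_ml, 0)

  bad <- st; bad$nominal_spacing_mm <- -1; bad$positions_mm <- NULL
  expect_error(compute_volumes(bad), "spacing")
})

test_that("digitized ellipsoid volume is within 1% of the analytic value", {
  # semi-axes 60 x 35 x 25 mm at 1 mm isotropic voxels
  st <- make_ellipsoid_stack(centers = c(70, 70, 30),
                             semi = c(60, 35, 25),
                             dims = c(140, 140, 60), spacing = c(1, 1, 1))
  analytic <- 4 / 3 * pi * 60 * 35 * 25 / 1000   # 219.9 mL
  lab <- st; lab$mask[lab$mask == 1L] <- 1L
  v <- compute_volumes(split_left_right(st))
  expect_lt(abs(v$total_ml - analytic) / analytic, 0.01)
})

test_that("halving the voxel size shrinks the digitization error", {
  analytic <- 4 / 3 * pi * 30 * 20 * 16 / 1000
  err <- sapply(c(4, 2), function(h) {
    st <- make_ellipsoid_stack(centers = c(40, 40, 40), semi = c(30, 20, 16),
                               dims = c(80, 80, 80) / h,
                               spacing = c(h, h, h))
    abs(tkv(st)$total_ml - analytic) / analytic
  })
  expect_lt(err[2], err[1])
})

test_that("two disjoint bodies are assigned right/left by L-R centroid", {
  # patient-left = larger column coordinate; right kidney at small cols
  st <- make_ellipsoid_stack(
    centers = rbind(c(40, 30, 30), c(40, 90, 30)),
    semi = rbind(c(14, 14, 14), c(10, 10, 10)))
  lab <- split_left_right(st)
  counts <- tabulate(lab$mask, 2)
  oracle <- oracle_label(st$mask)
  sizes <- sort(tabulate(oracle[oracle > 0]), decreasing = TRUE)
  expect_equal(sort(counts, decreasing = TRUE), sizes)
  # the body at small column coordinate is the (larger) right kidney
  expect_gt(counts[1], counts[2])
  v <- compute_volumes(lab)
  expect_equal(v$total_ml, v$right_ml + v$left_ml)
  expect_gt(v$right_ml, v$left_ml)
})

test_that("stray voxels remote from the two largest components are removed", {
  st <- make_ellipsoid_stack(
    centers = rbind(c(40, 30, 30), c(40, 90, 30)),
    semi = rbind(c(12, 12, 12), c(12, 12, 12)))
  st$mask[2, 58, 2] <- 1L   # 2-voxel blob far from both kidneys
  st$mask[3, 58, 2] <- 1L
  lab <- split_left_right(st)
  expect_equal(attr(lab, "n_stray_voxels"), 2L)
  expect_equal(sum(lab$mask > 0), sum(st$mask > 0) - 2L)
})

test_that("a single fused component splits at the image mid-plane", {
  # one ball centered on the mid-plane of an even-width grid
  st <- make_ellipsoid_stack(centers = c(40, 60, 30), semi = c(16, 16, 16),
                             dims = c(40, 60, 30))
  lab <- split_left_right(st)
  counts <- tabulate(lab$mask, 2)
  expect_equal(counts[1], counts[2])
  expect_equal(sum(counts), sum(st$mask > 0))
})

test_that("left/right assignment ignores component discovery order", {
  st1 <- make_ellipsoid_stack(
    centers = rbind(c(20, 30, 30), c(30, 90, 30)),
    semi = rbind(c(12, 12, 12), c(13, 13, 13)))
  # flip slice order: discovery order changes, assignment must not
  st2 <- st1
  st2$mask <- st1$mask[, , rev(seq_len(dim(st1$mask)[3]))]
  v1 <- compute_volumes(split_left_right(st1))
  v2 <- compute_volumes(split_left_right(st2))
  expect_equal(v1$right_ml, v2$right_ml)
  expect_equal(v1$left_ml, v2$left_ml)
})

test_that("volumes are additive over disjoint masks", {
  a <- make_ellipsoid_stack(centers = c(40, 30, 30), semi = c(12, 12, 12))
  b <- make_ellipsoid_stack(centers = c(40, 90, 30), semi = c(10, 10, 10))
  both <- a; both$mask <- a$mask + b$mask
  expect_equal(tkv(both)$total_ml,
               tkv(a)$total_ml + tkv(b)$total_ml)
})

test_that("height-adjusted TKV divides by height in meters", {
  expect_equal(ht_tkv(1700, 1.70), 1000)
  expect_equal(ht_tkv(0, 1.80), 0)
  expect_equal(round(ht_tkv(1279, 1.636)), 782)
  expect_true(is.na(ht_tkv(1700, NA)))
  expect_error(ht_tkv(1700, 0), "positive")
})

test_that("effective spacing prefers recorded positions over the nominal value", {
  mask <- array(1L, c(4, 4, 5))
  st <- slice_stack(mask, positions_mm = c(0, 5, 10, 15, 20),
                    pixel_spacing_mm = c(1, 1), nominal_spacing_mm = 4,
                    orientation = "axial", sequence = "AX_T1")
  expect_equal(effective_spacing(st), 5)
  st$positions_mm <- NULL
  expect_equal(effective_spacing(st), 4)
})
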