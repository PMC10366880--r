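# Detector behavior on constructed fixtures. Two digitized kidneys, then
# hand-applied perturbations with known signatures.

# z-center 61 mm sits between slice positions, so no two digitized slices
# of the smooth ellipsoids are exactly mirror-identical
two_kidney_stack <- function(sequence = "AX_T2", spacing = c(2, 2, 4)) {
  make_ellipsoid_stack(
    centers = rbind(c(40, 30, 61), c(40, 90, 61)),
    semi = rbind(c(16, 14, 40), c(16, 14, 40)),
    dims = c(40, 60, 30), spacing = spacing, sequence = sequence)
}

test_that("smooth stacks stay below the discontinuity threshold", {
  st <- two_kidney_stack()
  p <- slice_discontinuity_profile(st)
  expect_gt(nrow(p), 0)
  expect_true(all(p$score < 0.35))
  expect_null(detect_breathing(st))
  expect_null(detect_breath_hold_mismatch(st))
})

test_that("an in-plane shift by one kidney radius scores at least 0.5", {
  st <- two_kidney_stack()
  k <- 15   # mid-kidney slice
  r_px <- round(sqrt(sum(st$mask[, , k] == 1) / pi))  # single kidney radius
  sl <- st$mask[, , k]
  st$mask[, , k] <- rbind(sl[-seq_len(r_px), ],
                          matrix(0L, r_px, ncol(sl)))
  p <- slice_discontinuity_profile(st)
  expect_gte(max(p$score[p$junction %in% c(k - 1, k)]), 0.5)
})

test_that("duplicated adjacent slices have Dice 1 and junction score 0", {
  st <- two_kidney_stack()
  st$mask[, , 16] <- st$mask[, , 15]
  p <- slice_discontinuity_profile(st)
  j <- p[p$junction == 15, ]
  expect_true(all(j$dice == 1))
  expect_true(all(j$score == 0))
})

test_that("breathing fires on scattered junctions but never on axial T1", {
  st <- two_kidney_stack()
  shift_rows <- function(sl, d) {
    out <- matrix(0L, nrow(sl), ncol(sl))
    src <- seq_len(nrow(sl)) - d
    ok <- src >= 1 & src <= nrow(sl)
    out[which(ok), ] <- sl[src[ok], ]
    out
  }
  for (k in 10:12) st$mask[, , k] <- shift_rows(st$mask[, , k], 9L)
  for (k in 18:20) st$mask[, , k] <- shift_rows(st$mask[, , k], -9L)
  fl <- detect_breathing(st)
  expect_s3_class(fl, "qc_flag")
  expect_equal(fl$error_type, "BREATHING_MOTION")
  expect_false(fl$correctable)

  st_t1 <- st; st_t1$sequence <- "AX_T1"
  expect_null(detect_breathing(st_t1))
  # with scattered junctions the breath-hold detector must not fire either
  expect_null(detect_breath_hold_mismatch(st))
})

test_that("a single dominant junction classifies as breath-hold, not breathing", {
  st <- two_kidney_stack(sequence = "AX_T1")
  shift_rows <- function(sl, d) {
    out <- matrix(0L, nrow(sl), ncol(sl))
    src <- seq_len(nrow(sl)) - d
    ok <- src >= 1 & src <= nrow(sl)
    out[which(ok), ] <- sl[src[ok], ]
    out
  }
  for (k in 16:30) st$mask[, , k] <- shift_rows(st$mask[, , k], 10L)
  fl <- detect_breath_hold_mismatch(st)
  expect_s3_class(fl, "qc_flag")
  expect_equal(fl$evidence$junction, 15)
  expect_null(detect_breathing(st))  # 3D sequence; also only one junction
  cls <- classify_exam_errors(list(AX_T1 = st))
  expect_length(cls$flags, 1)
  expect_equal(cls$flags[[1]]$error_type, "BREATH_HOLD_MISMATCH")
})

test_that("composing is detected from overlapping recorded positions", {
  mask <- array(1L, c(6, 6, 8))
  st <- slice_stack(mask, positions_mm = c(0, 5, 10, 15, 10, 15, 20, 25),
                    pixel_spacing_mm = c(1, 1), nominal_spacing_mm = 5,
                    orientation = "axial", sequence = "AX_T2")
  fl <- detect_composing_overlap(st)
  expect_s3_class(fl, "qc_flag")
  expect_equal(unname(fl$evidence$overlap_range_mm), c(10, 15))
  expect_true(fl$correctable)

  mono <- slice_stack(mask, positions_mm = seq(0, 35, by = 5),
                      pixel_spacing_mm = c(1, 1), nominal_spacing_mm = 5,
                      orientation = "axial", sequence = "AX_T2")
  expect_null(detect_composing_overlap(mono))

  nop <- mono; nop$positions_mm <- NULL
  expect_identical(detect_composing_overlap(nop), "NOT_EVALUABLE")
  cls <- classify_exam_errors(list(AX_T2 = nop))
  expect_equal(cls$not_evaluable$detector, "COMPOSING_OVERLAP")
})

test_that("incomplete field of view needs kidney on the boundary", {
  st <- two_kidney_stack()
  expect_null(detect_incomplete_fov(st))

  # crop slices from the top so the kidney reaches the last slice
  cropped <- st
  keep <- 1:22
  cropped$mask <- cropped$mask[, , keep]
  cropped$positions_mm <- cropped$positions_mm[keep]
  fl <- detect_incomplete_fov(cropped)
  expect_s3_class(fl, "qc_flag")
  expect_false(fl$correctable)

  # the missing volume matches the analytic ellipsoid cap within 5%
  v_full <- tkv(st)$total_ml
  v_crop <- tkv(cropped)$total_ml
  c_ax <- 40; z0 <- 61                      # semi-axis and center (mm)
  z_cut <- cropped$positions_mm[22] + 2     # boundary of retained voxels
  h <- (z0 + c_ax) - z_cut                  # cap height, per kidney
  a <- 16; b <- 14
  cap <- pi * a * b * h^2 * (3 * c_ax - h) / (3 * c_ax^2) / 1000
  expect_lt(abs((v_full - v_crop) - 2 * cap) / (2 * cap), 0.05)

  # a sub-threshold border artifact does not trigger the flag
  tiny <- st
  tiny$mask[1, 10, 10] <- 1L
  expect_null(detect_incomplete_fov(tiny))
  # above the contact-area threshold it does
  big <- st
  big$mask[1, 10:30, 10] <- 1L
  expect_s3_class(detect_incomplete_fov(big), "qc_flag")
})

test_that("detectors do not mutate their input and are deterministic", {
  st <- two_kidney_stack()
  before <- st$mask
  p1 <- slice_discontinuity_profile(st)
  invisible(detect_breathing(st))
  invisible(detect_breath_hold_mismatch(st))
  invisible(detect_composing_overlap(st))
  invisible(detect_incomplete_fov(st))
  expect_identical(st$mask, before)
  p2 <- slice_discontinuity_profile(st)
  expect_identical(p1, p2)
})

test_that("composing takes precedence when several detectors fire", {
  st <- two_kidney_stack()
  # composing: duplicate a position range; breathing: shifted slice subsets
  n <- dim(st$mask)[3]
  idx <- c(1:16, 15:16, 17:n)
  st$mask <- st$mask[, , idx]
  st$positions_mm <- st$positions_mm[idx]
  shift_rows <- function(sl, d) {
    out <- matrix(0L, nrow(sl), ncol(sl))
    src <- seq_len(nrow(sl)) - d
    ok <- src >= 1 & src <= nrow(sl)
    out[which(ok), ] <- sl[src[ok], ]
    out
  }
  for (k in 8:9) st$mask[, , k] <- shift_rows(st$mask[, , k], 9L)
  for (k in 22:23) st$mask[, , k] <- shift_rows(st$mask[, , k], -9L)
  cls <- classify_exam_errors(list(AX_T2 = st))
  expect_length(cls$flags, 1)
  expect_equal(cls$flags[[1]]$error_type, "COMPOSING_OVERLAP")
  expect_true("BREATHING_MOTION" %in% cls$flags[[1]]$evidence$also_detected)
})
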