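test_that("percent change is relative to the pre-correction volume", {
  expect_equal(round(correction_pct_change(3741, 3592), 1), 4.0)
  expect_equal(correction_pct_change(100, 100), 0)
})

test_that("deleting duplicates halves a fully duplicated stack", {
  st <- make_ellipsoid_stack(centers = rbind(c(40, 30, 30), c(40, 90, 30)),
                             semi = rbind(c(14, 12, 20), c(14, 12, 20)))
  n <- dim(st$mask)[3]
  dup <- st
  idx <- rep(seq_len(n), each = 2)
  dup$mask <- st$mask[, , idx]
  dup$positions_mm <- st$positions_mm[idx]
  corrected <- delete_duplicate_slices(dup, seq(2, 2 * n, by = 2))
  expect_equal(tkv(corrected)$total_ml, tkv(dup)$total_ml / 2)
  expect_equal(tkv(corrected)$total_ml, tkv(st)$total_ml)

  # no duplicates: identity
  expect_identical(delete_duplicate_slices(st, integer(0)), st)
  # refusing to delete the whole kidney span
  span <- which(colSums(st$mask > 0, dims = 2) > 0)
  expect_error(delete_duplicate_slices(st, span), "kidney span")
})

test_that("recomposing two interleaved acquisitions recovers the volume", {
  st <- make_ellipsoid_stack(centers = rbind(c(40, 30, 30), c(40, 90, 30)),
                             semi = rbind(c(14, 12, 20), c(14, 12, 20)))
  n <- dim(st$mask)[3]
  idx <- as.vector(rbind(seq_len(n), seq_len(n)))  # two copies interleaved
  comp <- st
  comp$mask <- st$mask[, , idx]
  comp$positions_mm <- st$positions_mm[idx]
  v_bad <- tkv(comp)$total_ml
  expect_gt(v_bad, 1.9 * tkv(st)$total_ml)
  fixed <- recompose_stack(comp)
  expect_lt(abs(tkv(fixed)$total_ml - tkv(st)$total_ml) /
              tkv(st)$total_ml, 0.005)

  # monotone unique positions: identity
  same <- recompose_stack(st)
  expect_identical(same$mask, st$mask)

  # idempotence
  twice <- recompose_stack(fixed)
  expect_identical(twice$mask, fixed$mask)
})

test_that("volume scales with recorded spacing, not the nominal value", {
  st <- make_ellipsoid_stack(centers = rbind(c(40, 30, 30), c(40, 90, 30)),
                             semi = rbind(c(14, 12, 20), c(14, 12, 20)),
                             spacing = c(2, 2, 4))
  v_nominal <- tkv(st)$total_ml
  # recorded positions are actually 5 mm apart
  st5 <- st
  st5$positions_mm <- (seq_len(dim(st$mask)[3]) - 1) * 5
  expect_equal(tkv(st5)$total_ml, v_nominal * 5 / 4)
})

test_that("correction policy: recompose composing, delete breath-hold dups, exclude the rest", {
  cfg <- test_config(seed = 31)
  ex <- generate_exam(cfg, 1, observers = 1, inject = FALSE)
  stacks <- ex$stacks[[1]]
  clean_tkv <- sapply(stacks, function(s) tkv(s)$total_ml)

  inj_c <- inject_error(stacks[["AX_T2"]], "COMPOSING_OVERLAP", seed = 5)
  inj_b <- inject_error(stacks[["COR_T2"]], "BREATHING_MOTION", seed = 6)
  stacks[["AX_T2"]] <- inj_c$stack
  stacks[["COR_T2"]] <- inj_b$stack
  cls <- classify_exam_errors(stacks)
  types <- vapply(cls$flags, `[[`, "", "error_type")
  expect_setequal(types, c("COMPOSING_OVERLAP", "BREATHING_MOTION"))
  out <- apply_corrections(stacks, cls$flags)
  expect_equal(out$excluded, "COR_T2")
  rec <- out$records
  expect_equal(rec$action[rec$sequence == "AX_T2"], "RECOMPOSE")
  expect_equal(rec$action[rec$sequence == "COR_T2"], "NONE")
  # recomposed volume returns to the clean value
  v_fixed <- tkv(out$stacks[["AX_T2"]])$total_ml
  expect_lt(abs(v_fixed - clean_tkv[["AX_T2"]]) / clean_tkv[["AX_T2"]], 0.005)
  # applying corrections a second time changes nothing
  cls2 <- classify_exam_errors(out$stacks)
  types2 <- vapply(cls2$flags, `[[`, "", "error_type")
  expect_false("COMPOSING_OVERLAP" %in% types2)
})

test_that("breath-hold duplicates are identified and deleted exactly", {
  cfg <- test_config(seed = 32)
  ex <- generate_exam(cfg, 2, observers = 1, inject = FALSE)
  st <- ex$stacks[[1]][["AX_T1"]]
  v0 <- tkv(st)$total_ml
  # force the duplicated (positive) variant
  mag <- list(median_pct = c(AX_T1 = 5), sigma = 0.3, p_major = 1)
  inj <- inject_error(st, "BREATH_HOLD_MISMATCH", magnitude = mag, seed = 9)
  expect_equal(inj$record$action, "duplicate")
  fl <- detect_breath_hold_mismatch(inj$stack)
  expect_true(fl$correctable)
  expect_equal(length(fl$affected_slices), inj$record$k)
  fixed <- delete_duplicate_slices(inj$stack, fl$affected_slices)
  expect_equal(tkv(fixed)$total_ml, v0, tolerance = 1e-6)
})
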