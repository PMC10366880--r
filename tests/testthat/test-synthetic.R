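# Generator contracts: volume control, determinism, injection bookkeeping.

test_that("identity configuration digitizes the true volume within 1%", {
  cfg <- test_config(
    sequence_biases = setNames(rep(0, 5), tkv_sequences()),
    observer_cv = 0, seed = 21)
  ex <- generate_exam(cfg, 1, observers = 1, inject = FALSE)
  for (sq in tkv_sequences()) {
    v <- tkv(ex$stacks[[1]][[sq]])$total_ml
    expect_lt(abs(v / ex$truth$true_tkv_ml - 1), 0.01)
  }
})

test_that("a +1.2% axial T2 bias appears in the digitized volume", {
  cfg <- test_config(observer_cv = 0, seed = 22)
  ratios <- sapply(1:3, function(i) {
    ex <- generate_exam(cfg, i, sequences = "AX_T2", observers = 1,
                        inject = FALSE)
    tkv(ex$stacks[[1]][["AX_T2"]])$total_ml / ex$truth$true_tkv_ml
  })
  expect_true(all(abs(ratios - 1.012) < 0.01))
})

test_that("the same seed reproduces masks and truth bit for bit", {
  cfg <- test_config(seed = 23)
  a <- generate_exam(cfg, 3, observers = 2)
  b <- generate_exam(cfg, 3, observers = 2)
  expect_identical(a$stacks, b$stacks)
  expect_identical(a$truth, b$truth)
  # a different exam index gives different anatomy
  c2 <- generate_exam(cfg, 4, observers = 1)
  expect_false(identical(a$truth$true_tkv_ml, c2$truth$true_tkv_ml))
})

test_that("observer noise imposes the configured volume CV", {
  cfg <- test_config(observer_cv = 0.008, seed = 24)
  sdlog <- sqrt(log(1 + 0.008^2))
  set.seed(1)
  draws <- exp(rnorm(4000, -sdlog^2 / 2, sdlog))
  expect_equal(sd(draws) / mean(draws), 0.008, tolerance = 0.05)
  # two observers of one exam differ, with the right scale
  ex <- generate_exam(cfg, 1, sequences = "AX_T2", observers = 2,
                      inject = FALSE)
  v1 <- tkv(ex$stacks[[1]][["AX_T2"]])$total_ml
  v2 <- tkv(ex$stacks[[2]][["AX_T2"]])$total_ml
  expect_false(v1 == v2)
  expect_lt(abs(v1 / v2 - 1), 0.05)
})

test_that("removing slices debits exactly their summed area times spacing", {
  cfg <- test_config(seed = 25)
  ex <- generate_exam(cfg, 1, sequences = "COR_T2", observers = 1,
                      inject = FALSE)
  st <- ex$stacks[[1]][["COR_T2"]]
  v0 <- tkv(st)$total_ml
  # negative-deviation breathing: interior slices removed
  mag <- list(median_pct = c(COR_T2 = -6), sigma = 0.3, p_major = 1)
  inj <- inject_error(st, "BREATHING_MOTION", magnitude = mag, seed = 4)
  expect_equal(inj$record$action, "remove")
  px_area <- prod(st$pixel_spacing_mm)
  t_mm <- st$nominal_spacing_mm
  a_removed <- sum(colSums(st$mask > 0, dims = 2)[inj$record$slices]) * px_area
  v1 <- tkv(inj$stack)$total_ml
  expect_equal(v0 - v1, a_removed * t_mm / 1000, tolerance = 1e-9)
  expect_equal(v1 - v0, inj$record$expected_dv_ml, tolerance = 1e-9)
})

test_that("injection bookkeeping matches the realized volume for all types", {
  cfg <- test_config(seed = 26)
  ex <- generate_exam(cfg, 2, observers = 1, inject = FALSE)
  cases <- list(BREATHING_MOTION = "AX_T2", BREATH_HOLD_MISMATCH = "AX_T1",
                COMPOSING_OVERLAP = "AX_SSFP", INCOMPLETE_KIDNEY = "AX_T1")
  for (ty in names(cases)) {
    st <- ex$stacks[[1]][[cases[[ty]]]]
    v0 <- tkv(st)$total_ml
    inj <- inject_error(st, ty, seed = 13)
    v1 <- tkv(inj$stack)$total_ml
    expect_equal(v1 - v0, inj$record$expected_dv_ml, tolerance = 1e-6,
                 label = ty)
  }
})

test_that("magnitude zero is an explicit no-op", {
  cfg <- test_config(seed = 27)
  ex <- generate_exam(cfg, 1, sequences = "AX_T2", observers = 1,
                      inject = FALSE)
  st <- ex$stacks[[1]][["AX_T2"]]
  inj <- inject_error(st, "BREATHING_MOTION", magnitude = 0, seed = 1)
  expect_identical(inj$stack, st)
  expect_equal(inj$record$action, "noop")
})

test_that("ineligible error/sequence combinations are refused", {
  cfg <- test_config(seed = 28)
  ex <- generate_exam(cfg, 1, sequences = c("AX_T1", "COR_T2"),
                      observers = 1, inject = FALSE)
  expect_error(inject_error(ex$stacks[[1]][["AX_T1"]], "BREATHING_MOTION"),
               "not eligible")
  expect_error(inject_error(ex$stacks[[1]][["COR_T2"]], "COMPOSING_OVERLAP"),
               "not eligible")
})

test_that("a grid too small for the anatomy fails with the exam named", {
  cfg <- test_config(fov_mm = c(x = 120, y = 100, z = 120), seed = 29)
  expect_error(generate_exam(cfg, 7), "exam 7")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(sequence_biases = setNames(
    c(0.6, 0, 0, 0, 0), tkv_sequences())))
  bad_rates <- default_error_rates(); bad_rates[1, 1] <- 1.5
  expect_error(synthetic_config(error_rates = bad_rates))
})

test_that("truth ledger carries one row per injected error", {
  cfg <- test_config(n_exams = 2, seed = 30,
                     error_rates = default_error_rates() * 4)
  sim <- simulate_cohort(cfg)
  led <- truth_ledger(sim$truths)
  n_err <- sum(vapply(sim$truths, function(t) length(t$errors), 1L))
  expect_equal(sum(!is.na(led$error_type)), n_err)
  expect_true(all(led$true_tkv_ml > 0))
})
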