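# ATR correction, rubberband baseline, triglyceride subtraction.

test_that("ATR multiplier is nu/nu_ref and the config guards its geometry", {
  cfg <- atr_config()
  g <- grid_1k()
  s <- ir_spectrum(g, rep(1, length(g)))
  out <- atr_correct(s, cfg)
  i_ref <- which(g == 1000)
  expect_equal(out$absorbance[i_ref], 1)            # multiplier 1 at nu_ref
  expect_equal(out$absorbance[which(g == 2000)], 2) # exactly 2 at 2 nu_ref
  expect_error(atr_correct(out, cfg), "already")
  # total internal reflection condition
  expect_error(atr_config(crystal_index = 1.5, sample_index = 1.4,
                          incidence_deg = 45), "total internal reflection")
})

test_that("penetration depth matches the closed form for Ge/serum", {
  # lambda = 10 um, n1 = 4, theta = 45 deg, n2 = 1.5
  expect_equal(penetration_depth(1000, atr_config()), 0.664, tolerance = 1e-3)
  d <- 10 / (2 * pi * 4 * sqrt(0.5 - (1.5 / 4)^2))
  expect_equal(penetration_depth(1000, atr_config()), d, tolerance = 1e-12)
})

test_that("ATR correction is linear in the spectrum", {
  g <- grid_1k()
  y1 <- gauss(g, 1650, 12, 0.8)
  y2 <- gauss(g, 2930, 14, 0.4)
  lhs <- atr_correct(ir_spectrum(g, 2 * y1 + 3 * y2))
  rhs1 <- atr_correct(ir_spectrum(g, y1))
  rhs2 <- atr_correct(ir_spectrum(g, y2))
  expect_equal(lhs$absorbance, 2 * rhs1$absorbance + 3 * rhs2$absorbance,
               tolerance = 1e-14)
})

test_that("rubberband removes affine baselines exactly", {
  g <- grid_1k()
  out <- baseline_rubberband(ir_spectrum(g, 0.0002 * g + 0.05))
  expect_true(all(abs(out$absorbance) < 1e-12))
  # all-equal absorbance -> all zeros, not an error
  flat <- baseline_rubberband(ir_spectrum(g, rep(0.3, length(g))))
  expect_true(all(flat$absorbance == 0))
})

test_that("rubberband leaves an isolated Gaussian essentially unchanged", {
  g <- grid_1k()
  y <- gauss(g, 2000, 15, 1)
  out <- baseline_rubberband(ir_spectrum(g, y))
  expect_equal(out$absorbance, y, tolerance = 1e-10)
})

test_that("rubberband recovers a Gaussian from an affine ramp", {
  g <- grid_1k()
  y <- gauss(g, 2000, 15, 0.7) + 0.0001 * g + 0.02
  out <- baseline_rubberband(ir_spectrum(g, y))
  # oracle: dense O(n^2) brute-force lower hull on a coarser copy
  gc <- seq(900, 3200, 10)
  yc <- gauss(gc, 2000, 15, 0.7) + 0.0001 * gc + 0.02
  oracle <- yc - brute_lower_hull(gc, yc)
  expect_equal(max(out$absorbance), 0.7, tolerance = 0.01)
  expect_equal(max(oracle), max(out$absorbance), tolerance = 0.01)
})

test_that("rubberband is idempotent", {
  g <- grid_1k()
  y <- gauss(g, 1650, 12, 0.9) + gauss(g, 2930, 14, 0.3) + 0.0001 * g
  once <- baseline_rubberband(ir_spectrum(g, y))
  twice <- baseline_rubberband(once)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-12)
})

test_that("triglyceride correction: zero anchor signal is the identity", {
  g <- serorad:::.canonical_grid()
  ref <- tg_reference_synthetic(g)
  y <- gauss(g, 1650, 12, 0.9)  # protein only: nothing near 1737
  out <- tg_correct(ir_spectrum(g, y), ref)
  expect_equal(out$absorbance, y, tolerance = 1e-9)
  expect_equal(out$meta$tg_alpha, 0, tolerance = 1e-9)
})

test_that("triglyceride correction cancels an exact multiple of the reference", {
  g <- serorad:::.canonical_grid()
  ref <- tg_reference_synthetic(g)
  s <- ir_spectrum(g, 0.7 * ref$spectrum$absorbance)
  out <- tg_correct(s, ref)
  expect_equal(out$meta$tg_alpha, 0.7, tolerance = 1e-9)
  expect_true(all(abs(out$absorbance) <= 1e-9))
  # same via the literal peak-height estimator
  out2 <- tg_correct(ir_spectrum(g, 0.7 * ref$spectrum$absorbance), ref,
                     alpha_method = "peak")
  expect_true(all(abs(out2$absorbance) <= 1e-9))
})

test_that("triglyceride correction restores the protein CH2 peak within 2%", {
  g <- serorad:::.canonical_grid()
  ref <- tg_reference_synthetic(g)
  protein <- gauss(g, 2931, 14, 0.2) + gauss(g, 2958, 14, 0.22) +
    gauss(g, 1651, 10, 0.9)
  ph_protein <- peak_height(ir_spectrum(g, protein),
                            band_def("ch2", 2930))$height
  mixed <- tg_correct(ir_spectrum(g, protein + 0.3 * ref$spectrum$absorbance),
                      ref)
  ph_mixed <- peak_height(mixed, band_def("ch2", 2930))$height
  expect_equal(ph_mixed, ph_protein, tolerance = 0.02)
})

test_that("negative lipid estimates clamp to zero with a warning", {
  g <- serorad:::.canonical_grid()
  ref <- tg_reference_synthetic(g)
  dip <- -0.02 * gauss(g, 1737, 10)  # negative excursion at the anchor
  expect_warning(out <- tg_correct(ir_spectrum(g, dip), ref), "clamped")
  expect_equal(out$meta$tg_alpha, 0)
})

test_that("preprocessing chain commutes with global positive scaling", {
  p <- small_preset(noise_sd = 0)
  s <- simulate_series(p, seed = 3)
  s5 <- s
  s5$absorbance <- 5 * s$absorbance
  a <- preprocess_series(s, tg = TRUE)
  b <- preprocess_series(s5, tg = TRUE)
  expect_equal(b$absorbance, 5 * a$absorbance, tolerance = 1e-10)
})

test_that("ALS baseline flattens a curved background under a band", {
  g <- seq(900, 2000, 2)
  bg <- 0.2 + 1e-4 * (g - 900) - 3e-8 * (g - 900)^2
  y <- gauss(g, 1650, 12, 0.8) + bg
  out <- baseline_als(ir_spectrum(g, y))
  expect_equal(max(out$absorbance), 0.8, tolerance = 0.05)
  expect_lt(abs(stats::median(out$absorbance)), 0.02)
})
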