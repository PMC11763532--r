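# Reading/writing series matrices, JCAMP directories, clinical tables,
# reports.

test_that("spectrum and series constructors validate and normalize grids", {
  s <- ir_spectrum(c(1002, 1001, 1000), c(3, 2, 1))
  expect_equal(s$wavenumbers, c(1000, 1001, 1002))
  expect_equal(s$absorbance, c(1, 2, 3))
  expect_error(ir_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(ir_spectrum(c(1, 2, 2), c(1, 2, 3)), "monotone")
  expect_error(ir_spectrum(c(1, 2, 3), c(1, NA, 3)), "finite")

  m <- matrix(1:6, nrow = 3)
  expect_error(dehydration_series(1:3, m[, 1, drop = FALSE]), "at least 2")
  ds <- dehydration_series(3:1, m)
  expect_equal(ds$wavenumbers, 1:3)
  expect_equal(ds$absorbance[, 1], c(3, 2, 1))
  expect_equal(ds$times, c(0, 0.791))
  expect_error(dehydration_series(1:3, m, times = c(1, 1)), "increasing")
})

test_that("matrix round-trip is the identity on the numeric payload", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # toy 3-point grid, two time points
  toy <- dehydration_series(c(1000, 1001, 1002),
                            cbind(c(0.1, 0.5, 0.2), c(0.2, 0.6, 0.3)))
  write_series_matrix(toy, tmp)
  back <- read_series_matrix(tmp)
  expect_equal(back$wavenumbers, toy$wavenumbers)
  expect_equal(unname(back$absorbance), unname(toy$absorbance))
  expect_equal(back$times, toy$times)

  # re-reading already-ascending data changes nothing (involution safety)
  write_series_matrix(back, tmp)
  again <- read_series_matrix(tmp)
  expect_identical(again$wavenumbers, back$wavenumbers)
  expect_identical(unname(again$absorbance), unname(back$absorbance))
})

test_that("descending matrices are reversed with absorbance co-reversed", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1002,0.2,0.3", "1001,0.5,0.6", "1000,0.1,0.2"), tmp)
  ds <- read_series_matrix(tmp)
  expect_equal(ds$wavenumbers, c(1000, 1001, 1002))
  expect_equal(ds$absorbance[, 1], c(0.1, 0.5, 0.2))
  expect_equal(ds$times, c(0, 0.791))  # synthesized cadence
})

test_that("a simulated 758-column export re-reads within write precision", {
  p <- small_preset(n_spectra = 758)
  s <- simulate_series(p, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_series_matrix(s, tmp)
  back <- read_series_matrix(tmp)
  expect_equal(ncol(back$absorbance), 758)
  expect_equal(back$times, s$times, tolerance = 1e-12)
  expect_equal(unname(back$absorbance), unname(s$absorbance),
               tolerance = 1e-12)
})

test_that("matrix reader rejects malformed input with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0.1", "1001,0.2"), tmp)
  expect_error(read_series_matrix(tmp), ">= 2 time columns")
  writeLines(c("1000,0.1,abc", "1001,0.2,0.3"), tmp)
  expect_error(read_series_matrix(tmp), "row|column|cell")
})

test_that("JCAMP directory reading assembles a series", {
  dir <- withr::local_tempdir()
  g <- seq(900, 3150, 2)
  y <- gauss(g, 1650, 12, 0.8)
  write_jcamp(file.path(dir, "a_01.jdx"), g, y)
  write_jcamp(file.path(dir, "a_02.jdx"), g, y)
  ds <- read_jcamp_dir(dir)
  expect_equal(ncol(ds$absorbance), 2)
  expect_equal(ds$absorbance[, 1], ds$absorbance[, 2])
  expect_equal(ds$absorbance[, 1], y, tolerance = 1e-6)
})

test_that("JCAMP wavelength units are rejected", {
  dir <- withr::local_tempdir()
  g <- seq(900, 3150, 2)
  write_jcamp(file.path(dir, "b.jdx"), g, gauss(g, 1650),
              xunits = "MICROMETERS")
  expect_error(read_jcamp_dir(dir), "XUNITS")
})

test_that("empty JCAMP directory is an input error", {
  dir <- withr::local_tempdir()
  expect_error(read_jcamp_dir(dir), "no JCAMP files")
})

test_that("offset JCAMP grids are interpolated onto the first file's grid", {
  dir <- withr::local_tempdir()
  g1 <- seq(900, 3150, 2)
  g2 <- g1 + 0.5
  f <- function(x) gauss(x, 1650, 12, 0.8) + gauss(x, 2930, 14, 0.3)
  write_jcamp(file.path(dir, "c_01.jdx"), g1, f(g1))
  write_jcamp(file.path(dir, "c_02.jdx"), g2, f(g2))
  ds <- read_jcamp_dir(dir)
  # manual linear interpolation check at three interior points
  for (nu in c(1644, 1650, 2930)) {
    i <- which(g1 == nu)
    manual <- f(g2[i - 1]) +
      (f(g2[i]) - f(g2[i - 1])) * (g1[i] - g2[i - 1]) / (g2[i] - g2[i - 1])
    expect_equal(ds$absorbance[i, 2], manual, tolerance = 1e-6)
  }
})

test_that("clinical tables are validated and ordered", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("followup_T,scr,albumin,utp,upcr",
               "90,1.1,3.2,400,1.9", "30,2.0,2.5,900,3.5"), tmp)
  cl <- read_clinical_table(tmp)
  expect_equal(cl$followup_T, c(30, 90))
  writeLines(c("followup_T,scr,albumin,utp,upcr",
               "30,-1,3.2,400,1.9"), tmp)
  expect_error(read_clinical_table(tmp), "non-negative")
  writeLines(c("followup_T,scr,albumin", "30,1,3.2"), tmp)
  expect_error(read_clinical_table(tmp), "missing columns")
})

test_that("report writing orders rows and round-trips psi values", {
  gaps1 <- list(Hp = 0.1, Hph = -0.25, Alb = 1 / 3, Lact = 0.2, Gly = 0.05)
  gaps0 <- list(Hp = 0, Hph = 0, Alb = 0, Lact = 0, Gly = 0)
  r1 <- followup_record(180, gaps1, hpi = 1.01)
  r0 <- followup_record(30, gaps0, hpi = 0.94)
  stem <- file.path(withr::local_tempdir(), "run")
  paths <- write_report(list(r1, r0), stem)
  tab <- read_gap_table(paths[["gaps"]])
  expect_equal(nrow(tab), 10)
  # ordered by followup then index name; record with all-zero gaps first
  expect_equal(tab$followup_T, rep(c(30, 180), each = 5))
  expect_equal(tab$index[1:5], sort(names(gaps0)))
  expect_true(all(tab$psi[1:5] == 0))
  # 12-significant-digit round trip
  expect_equal(tab$psi[tab$followup_T == 180 & tab$index == "Alb"], 1 / 3,
               tolerance = 1e-12)
  rep_doc <- jsonlite::read_json(paths[["report"]])
  expect_equal(length(rep_doc$records), 2)
  expect_equal(rep_doc$records[[2]]$ppf, ppf(gaps1))
  expect_error(write_report(list(), stem), "no records")
})

test_that("canonical-grid interpolation enforces spectral coverage", {
  toy <- dehydration_series(c(1000, 1001, 1002),
                            cbind(c(0.1, 0.5, 0.2), c(0.2, 0.6, 0.3)))
  expect_error(to_canonical_grid(toy), "900-3100")
  p <- small_preset()
  s <- simulate_series(p, seed = 1)
  expect_identical(to_canonical_grid(s), s)  # already canonical: no-op
})
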