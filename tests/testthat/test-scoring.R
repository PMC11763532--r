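# PPF, biomarker normalization and score, timeline correlations.

test_that("ppf combines the five gaps with the signed unit weights", {
  zero <- list(Lact = 0, Gly = 0, Hp = 0, Hph = 0, Alb = 0)
  expect_equal(ppf(zero), 0)
  ones <- list(Lact = 1, Gly = 1, Hp = 1, Hph = 1, Alb = 1)
  expect_equal(ppf(ones), 3)
  expect_equal(ppf(list(Lact = 0.1, Gly = 0.2, Hp = 0.3, Hph = 0.4,
                        Alb = 0.5)), 0.7, tolerance = 1e-12)
  expect_error(ppf(list(Lact = 1, Gly = 1, Hp = 1, Hph = 1)), "Alb")
})

test_that("ppf is linear and term order is irrelevant", {
  set.seed(13)
  for (i in 1:20) {
    g1 <- as.list(setNames(rnorm(5), c("Lact", "Gly", "Hp", "Hph", "Alb")))
    g2 <- as.list(setNames(rnorm(5), c("Lact", "Gly", "Hp", "Hph", "Alb")))
    gsum <- Map(function(a, b) 2 * a + 3 * b, g1, g2)
    expect_equal(ppf(gsum), 2 * ppf(g1) + 3 * ppf(g2), tolerance = 1e-12)
    expect_equal(ppf(g1[sample(5)]), ppf(g1))
    flipped <- g1
    flipped$Hph <- -g1$Hph
    expect_equal(ppf(flipped) - ppf(g1), 2 * g1$Hph, tolerance = 1e-12)
  }
})

test_that("followup_record recomputes and checks the PPF", {
  gaps <- list(Lact = 0.1, Gly = 0.2, Hp = 0.3, Hph = 0.4, Alb = 0.5)
  r <- followup_record(30, gaps, hpi = 1.0)
  expect_equal(r$ppf, 0.7, tolerance = 1e-12)
  expect_error(followup_record(30, gaps, ppf = 0.5), "inconsistent")
})

test_that("min-max normalization maps each biomarker onto [0, 1]", {
  cl <- data.frame(followup_T = c(0, 30, 90), scr = c(1, 2, 1.5),
                   albumin = c(2.5, 3.5, 4.5), utp = c(900, 400, 100),
                   upcr = c(3.5, 1.9, 0.2))
  nm <- normalize_biomarkers(cl)
  expect_equal(nm$scr, c(0, 1, 0.5))
  expect_equal(range(nm$utp), c(0, 1))
  # constant biomarker degenerates to 0 with a warning
  cl$albumin <- 3
  expect_warning(nm2 <- normalize_biomarkers(cl), "constant")
  expect_true(all(nm2$albumin == 0))
  # idempotence: renormalizing normalized values changes nothing
  expect_equal(normalize_biomarkers(nm)[-1], nm[-1], tolerance = 1e-12)
})

test_that("z-score normalization yields mean 0 and SD 1 per biomarker", {
  set.seed(21)
  cl <- data.frame(followup_T = 1:8, scr = runif(8, 0.5, 3),
                   albumin = runif(8, 2, 5), utp = runif(8, 50, 900),
                   upcr = runif(8, 0.1, 4))
  nm <- normalize_biomarkers(cl, method = "zscore")
  for (cc in c("scr", "albumin", "utp", "upcr")) {
    expect_equal(mean(nm[[cc]]), 0, tolerance = 1e-12)
    expect_equal(sd(nm[[cc]]), 1, tolerance = 1e-12)
  }
})

test_that("biomarker score is UTP + UPCR + Scr - albumin", {
  expect_equal(biomarker_score(list(utp = 0, upcr = 0, scr = 0, albumin = 0)),
               0)
  expect_equal(biomarker_score(list(utp = 1, upcr = 1, scr = 1, albumin = 1)),
               2)
  expect_equal(biomarker_score(list(utp = 0.5, upcr = 0.2, scr = 0.1,
                                    albumin = 0.9)), -0.1, tolerance = 1e-12)
  expect_error(biomarker_score(list(utp = 1, upcr = 1, scr = 1)), "albumin")
})

mk_record <- function(T, phi_target, hpi = 1, clinical = NULL) {
  # build a gap set whose ppf equals phi_target (only Lact varies)
  gaps <- list(Lact = phi_target, Gly = 0, Hp = 0, Hph = 0, Alb = 0)
  followup_record(T, gaps, hpi = hpi, clinical = clinical)
}

test_that("timeline correlations recover perfect concordance and reversal", {
  phis <- c(0.1, 0.5, 0.9, 1.4)
  clin_up <- lapply(phis, function(v) {
    list(scr = v, albumin = 1 - v / 2, utp = 10 * v, upcr = v^2)
  })
  recs <- Map(function(T, v, cl) mk_record(T, v, clinical = cl),
              c(0, 30, 90, 180), phis, clin_up)
  tl <- patient_timeline("P1", recs)
  res <- correlate_timeline(tl)
  expect_equal(res$rho[res$spectral == "ppf" & res$clinical == "scr"], 1)
  expect_equal(res$rho[res$spectral == "ppf" & res$clinical == "score"], 1)
  expect_equal(res$rho[res$spectral == "ppf" & res$clinical == "albumin"], -1)
  expect_true(all(res$n == 4))
  expect_identical(attr(res, "multiplicity"), "uncorrected")
  expect_error(correlate_timeline(patient_timeline("P2", recs[1:2])), ">= 3")
})

test_that("noisy concordant series keep a high rank correlation", {
  set.seed(7)
  n <- 12
  score <- seq(0.1, 1.2, length.out = n)
  phi <- score + rnorm(n, 0, 0.01)
  recs <- Map(function(T, v, sc) {
    mk_record(T, v, clinical = list(scr = sc, albumin = 1, utp = sc,
                                    upcr = sc))
  }, seq(0, 330, 30), phi, score)
  # constant albumin in this fixture triggers the min-max degeneracy warning
  expect_warning(res <- correlate_timeline(patient_timeline("P3", recs)),
                 "constant")
  rho <- res$rho[res$spectral == "ppf" & res$clinical == "scr"]
  expect_gte(rho, 0.9)
})

test_that("a responder timeline shows strictly decreasing PPF", {
  # gaps trending linearly from an acute-like state toward the healthy preset
  acute <- small_preset("acute_6m")$ground_truth$psi
  healthy <- small_preset("healthy")$ground_truth$psi
  phis <- vapply(seq(0, 1, length.out = 4), function(f) {
    ppf(Map(function(a, h) (1 - f) * a + f * h, acute, healthy))
  }, numeric(1))
  expect_equal(phis[1], ppf(acute), tolerance = 1e-12)
  expect_equal(phis[4], ppf(healthy), tolerance = 1e-12)
  expect_gt(ppf(acute), ppf(healthy))  # disease activity raises Phi
  expect_true(all(diff(phis) < 0))
})

test_that("timeline construction requires strictly increasing follow-ups", {
  r1 <- mk_record(0, 0.1)
  r2 <- mk_record(0, 0.2)
  expect_error(patient_timeline("P4", list(r1, r2)), "strictly increasing")
  tl <- patient_timeline("P5", list(mk_record(30, 0.2), mk_record(0, 0.1)))
  expect_equal(vapply(tl$records, function(r) r$followup_T, numeric(1)),
               c(0, 30))
})
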