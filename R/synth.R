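# Synthetic dehydration-series generator with known ground truth.
#
# Physical picture: a water-dominated liquid-phase spectrum decays along a
# sigmoid into a dried-film solute spectrum. Solute band amplitudes
# interpolate linearly between a liquid-phase and a dried-film value as the
# water fraction drops; a triglyceride component (an exact multiple of the
# shipped reference shape) exercises the lipid correction; the emitted raw
# spectra carry the 1/nu evanescent-wave penetration-depth weighting that the
# pipeline's ATR correction undoes, plus i.i.d. Gaussian detector noise and a
# slow flat drift.

#' One synthetic absorption band
#'
#' @param name Band name.
#' @param center Center, cm^-1.
#' @param sigma Width (Gaussian SD or Lorentzian HWHM), cm^-1, > 0.
#' @param amp_liquid,amp_dried Peak amplitudes (AU) in the liquid phase and
#'   the dried film, >= 0.
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return A one-row data.frame.
#' @export
band_spec <- function(name, center, sigma, amp_liquid, amp_dried,
                      shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(sigma > 0, amp_liquid >= 0, amp_dried >= 0)
  data.frame(name = name, center = center, sigma = sigma,
             amp_liquid = amp_liquid, amp_dried = amp_dried, shape = shape,
             stringsAsFactors = FALSE)
}

.band_shape <- function(wavenumbers, center, sigma, shape) {
  if (shape == "lorentzian") {
    sigma^2 / ((wavenumbers - center)^2 + sigma^2)
  } else {
    exp(-(wavenumbers - center)^2 / (2 * sigma^2))
  }
}

# Baseline dried-film serum band table (healthy-like amplitudes, AU).
# sigma = 10 cm^-1 throughout except the CH stretching quartet (14 cm^-1).
# amp_liquid is expressed here as a fraction of amp_dried; bands whose
# hydration behaviour departs from the bulk (lactate, carbohydrate, amide II)
# carry slightly different fractions, which is what produces nonzero RAD
# gaps. The 2931 cm^-1 amplitude is a placeholder; presets solve it so the
# dried-film CH2/CH3 peak-height ratio equals the preset's target HPI.
.base_serum_bands <- function() {
  tab <- data.frame(
    name   = c("amideA", "amideB", "ch3_as", "ch2_as", "ch3_s", "ch2_s",
               "amideI", "amideII", "ch2_bend", "coo_bend", "amideIII_a",
               "amideIII_b", "coh_ser", "coh_lact", "glycan_cnc", "coc_carb"),
    center = c(3290, 3064, 2958, 2931, 2872, 2855, 1651, 1541, 1456, 1399,
               1314, 1243, 1171, 1122, 1078, 1030),
    sigma  = c(10, 10, 14, 14, 14, 14, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10),
    amp_dried = c(0.50, 0.08, 0.22, 0.20, 0.08, 0.05, 0.90, 0.60, 0.30, 0.33,
                  0.10, 0.12, 0.14, 0.10, 0.12, 0.12),
    liquid_frac = c(0.18, 0.18, 0.18, 0.18, 0.18, 0.18, 0.18, 0.20, 0.18,
                    0.20, 0.18, 0.18, 0.18, 0.25, 0.20, 0.22),
    stringsAsFactors = FALSE)
  tab$amp_liquid <- tab$amp_dried * tab$liquid_frac
  tab$shape <- "gaussian"
  tab[c("name", "center", "sigma", "amp_liquid", "amp_dried", "shape")]
}

# Disease presets differ from the healthy baseline only through band
# amplitudes: the dried CH2/CH3 target (HPI), dried amounts of the
# glycosylation/lactate bands (up in acute disease) and of the
# albumin-related bands (down in acute disease), and the liquid:dried
# amplitude ratios (`liquid_frac`) of the same bands. The latter control the
# RAD gaps: for a target band with liquid fraction f against a reference
# with fraction f_ref, the encoded gap is about (ref/amp) * (1 - f_ref/f),
# so analytes that stay spectroscopically active in the liquid phase
# (glycosylated IgG, lactate in acute disease) carry larger gaps.
.preset_params <- function(name) {
  switch(name,
    healthy   = list(target_hpi = 0.94, dried = c(), liquid_frac = c()),
    acute_6m  = list(target_hpi = 1.04,
                     dried = c(coc_carb = 0.18, coh_lact = 0.14,
                               coo_bend = 0.30, amideII = 0.55),
                     liquid_frac = c(coc_carb = 0.30, coh_lact = 0.32,
                                     coo_bend = 0.185, ch2_as = 0.24)),
    acute_12m = list(target_hpi = 1.01,
                     dried = c(coc_carb = 0.16, coh_lact = 0.12,
                               coo_bend = 0.31, amideII = 0.57),
                     liquid_frac = c(coc_carb = 0.26, coh_lact = 0.28,
                                     coo_bend = 0.19, ch2_as = 0.21)),
    chronic   = list(target_hpi = 0.95,
                     dried = c(coc_carb = 0.13, coh_lact = 0.11),
                     liquid_frac = c(coc_carb = 0.23, coh_lact = 0.26)),
    remission = list(target_hpi = 0.94,
                     dried = c(coc_carb = 0.13), liquid_frac = c()),
    stop("unknown preset '", name, "'", call. = FALSE))
}

# Solve the dried 2931 cm^-1 amplitude so that the measured peak-height ratio
# PH(2930 +/- 8)/PH(2960 +/- 8) of the noiseless dried protein film equals
# the target HPI. The neighbouring CH3 band bleeds ~16% of its height into
# the CH2 window (and vice versa), so a naive amplitude ratio would not
# reproduce the published peak-height ratio.
.solve_ch2_amp <- function(bands, target_hpi) {
  grid <- .canonical_grid()
  others <- bands[bands$name != "ch2_as", ]
  base <- rowSums(vapply(seq_len(nrow(others)), function(i) {
    others$amp_dried[i] *
      .band_shape(grid, others$center[i], others$sigma[i], others$shape[i])
  }, numeric(length(grid))))
  ch2 <- .band_shape(grid, bands$center[bands$name == "ch2_as"],
                     bands$sigma[bands$name == "ch2_as"], "gaussian")
  b1 <- band_def("ch2_as", 2930)
  b2 <- band_def("ch3_as", 2960)
  f <- function(a) {
    y <- base + a * ch2
    h1 <- .peak_height_num(grid, y, b1)[["height"]]
    h2 <- .peak_height_num(grid, y, b2)[["height"]]
    h1 / h2 - target_hpi
  }
  a3 <- bands$amp_dried[bands$name == "ch3_as"]
  stats::uniroot(f, c(0.05 * a3, 3 * a3), tol = 1e-12)$root
}

#' Construct a simulation preset
#'
#' A preset bundles the band table (with the CH2 stretch amplitude solved
#' from the target HPI), the water background, noise/drift levels and the
#' acquisition geometry. The five named presets encode the published
#' dried-film CH2/CH3 ratios: healthy 0.94, acute disease at 6 months 1.04,
#' at 12 months 1.01, chronic 0.95, remission 0.94.
#'
#' @param name One of `"healthy"`, `"acute_6m"`, `"acute_12m"`, `"chronic"`,
#'   `"remission"`.
#' @param n_spectra Spectra per run (default 758, >= 200).
#' @param dt Acquisition cadence, seconds (default 0.791).
#' @param noise_sd Detector noise SD, AU (default 0.002).
#' @param drift_amp Amplitude of the slow flat drift, AU (default 0.001).
#' @param lipid_frac Dried-film triglyceride amount in units of the
#'   reference's anchor-band height (default 0.12).
#' @param water_amp Liquid-phase water OH-stretch amplitude, AU (default 0.9).
#' @param water_decay_mid Sigmoid midpoint of the water decay, s (default
#'   300: the first 100 spectra, <= 79 s, are water-dominated and the last
#'   100, >= 520 s, are dried).
#' @param water_decay_rate Sigmoid rate, 1/s (default 0.03).
#' @param bands Optional replacement band table (as from [band_spec()] rows);
#'   the CH2 amplitude is still re-solved from `target_hpi`.
#' @param target_hpi Optional override of the preset's target dried-film
#'   CH2/CH3 peak-height ratio (> 0).
#' @return A `sim_preset` object; `$ground_truth` holds the target HPI and
#'   the analytic window-averaged RAD gaps for the five canonical indices.
#' @export
sim_preset <- function(name = c("healthy", "acute_6m", "acute_12m",
                                "chronic", "remission"),
                       n_spectra = 758, dt = 0.791, noise_sd = 0.002,
                       drift_amp = 0.001, lipid_frac = 0.12, water_amp = 0.9,
                       water_decay_mid = 300, water_decay_rate = 0.03,
                       bands = NULL, target_hpi = NULL) {
  name <- match.arg(name)
  pp <- .preset_params(name)
  if (is.null(target_hpi)) target_hpi <- pp$target_hpi
  stopifnot(target_hpi > 0, n_spectra >= 200, dt > 0, noise_sd >= 0,
            lipid_frac >= 0)
  if (is.null(bands)) {
    bands <- .base_serum_bands()
    frac <- bands$amp_liquid / bands$amp_dried
    names(frac) <- bands$name
    frac[names(pp$liquid_frac)] <- pp$liquid_frac
    for (nm in names(pp$dried)) {
      bands$amp_dried[bands$name == nm] <- pp$dried[[nm]]
    }
    bands$amp_liquid <- bands$amp_dried * frac[bands$name]
  }
  a2 <- .solve_ch2_amp(bands, target_hpi)
  frac2 <- bands$amp_liquid[bands$name == "ch2_as"] /
    bands$amp_dried[bands$name == "ch2_as"]
  bands$amp_dried[bands$name == "ch2_as"] <- a2
  bands$amp_liquid[bands$name == "ch2_as"] <- a2 * frac2
  preset <- structure(
    list(name = name, bands = bands, water_amp = water_amp,
         water_decay_mid = water_decay_mid,
         water_decay_rate = water_decay_rate, noise_sd = noise_sd,
         drift_amp = drift_amp, lipid_frac = lipid_frac,
         target_hpi = target_hpi, n_spectra = as.integer(n_spectra),
         dt = dt),
    class = "sim_preset")
  preset$ground_truth <- list(target_hpi = target_hpi,
                              psi = .psi_ground_truth(preset))
  preset
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf(
    "<sim_preset> '%s': %d spectra @ %.3f s, target HPI %.2f, noise %.3g AU\n",
    x$name, x$n_spectra, x$dt, x$target_hpi, x$noise_sd))
  invisible(x)
}

# Water fraction w(t): 1 in the liquid phase, -> 0 in the dried film.
.water_fraction <- function(preset, t) {
  1 / (1 + exp(preset$water_decay_rate * (t - preset$water_decay_mid)))
}

# Component basis on a grid: one column per solute band, one for the lipid
# reference shape, one for the water background.
.sim_basis <- function(preset, grid = .canonical_grid()) {
  bands <- preset$bands
  B <- vapply(seq_len(nrow(bands)), function(i) {
    .band_shape(grid, bands$center[i], bands$sigma[i], bands$shape[i])
  }, numeric(length(grid)))
  colnames(B) <- bands$name
  lipid <- tg_reference_synthetic(grid)$spectrum$absorbance
  water <- .band_shape(grid, 3350, 170, "gaussian") +
    0.3 * .band_shape(grid, 1640, 30, "gaussian")
  cbind(B, lipid = lipid, water = water)
}

# Component coefficients at times t: solutes interpolate liquid -> dried in
# the solid fraction s(t) = 1 - w(t); water follows w(t).
.sim_coefs <- function(preset, t) {
  w <- .water_fraction(preset, t)
  s <- 1 - w
  bands <- preset$bands
  C <- vapply(seq_along(t), function(k) {
    c(bands$amp_liquid + s[k] * (bands$amp_dried - bands$amp_liquid),
      lipid = preset$lipid_frac * (0.18 + s[k] * (1 - 0.18)),
      water = preset$water_amp * w[k])
  }, numeric(nrow(bands) + 2))
  rownames(C) <- c(bands$name, "lipid", "water")
  C
}

# Analytic window-averaged RAD gaps of the noiseless model: the measurement
# definition (window-maximum peak heights on the canonical grid) applied to
# the exact mixture, with the known lipid component removed exactly for
# TG-corrected indices. This is what a perfectly corrected pipeline would
# read; recovery tests compare the estimating pipeline against it.
.psi_ground_truth <- function(preset, window = 100,
                              indices = canonical_indices()) {
  grid <- .canonical_grid()
  B <- .sim_basis(preset, grid)
  n <- preset$n_spectra
  t_first <- (seq_len(window) - 1) * preset$dt
  t_last <- (seq.int(n - window + 1L, n) - 1) * preset$dt
  gap_of <- function(idx) {
    radmean <- function(tt) {
      C <- .sim_coefs(preset, tt)
      S <- B %*% C
      if (idx$tg_corrected) {
        S <- S - outer(B[, "lipid"], C["lipid", ])
      }
      h1 <- .peak_height_cols(grid, S, idx$nu1)$height
      h2 <- .peak_height_cols(grid, S, idx$nu2)$height
      mean((h1 - h2) / h1)
    }
    radmean(t_first) - radmean(t_last)
  }
  lapply(indices, gap_of)
}

# Run body in a deterministic RNG context, restoring the caller's state.
.with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  body()
}

#' Simulate one spectrum of a dehydration run
#'
#' Closed form: `A(nu, t) = w(t) W(nu) + sum_b amp_b(t) shape_b(nu) +
#' lipid(t) R(nu)`, with `w(t)` the sigmoid water fraction, `amp_b(t)`
#' interpolating liquid to dried amplitudes in the solid fraction
#' `s(t) = 1 - w(t)`, and `R` the triglyceride reference shape. The slow
#' drift offset and i.i.d. Gaussian noise (drawn from the current RNG state)
#' are added to the model absorbance, and the emitted raw spectrum is the sum
#' times the `nu_ref/nu` penetration-depth factor.
#'
#' @param preset A [sim_preset()].
#' @param t Dehydration time, seconds, in `[0, n_spectra * dt]`.
#' @param grid Wavenumber grid (default canonical).
#' @return An `ir_spectrum` in instrument (raw, ATR-weighted) units.
#' @export
simulate_spectrum <- function(preset, t, grid = .canonical_grid()) {
  stopifnot(inherits(preset, "sim_preset"), length(t) == 1,
            t >= 0, t <= preset$n_spectra * preset$dt)
  B <- .sim_basis(preset, grid)
  S <- as.numeric(B %*% .sim_coefs(preset, t))
  drift <- preset$drift_amp * sin(2 * pi * t / (preset$n_spectra * preset$dt))
  y <- S + drift
  if (preset$noise_sd > 0) y <- y + rnorm(length(grid), 0, preset$noise_sd)
  y <- y * (1000 / grid)  # penetration-depth weighting
  ir_spectrum(grid, y, meta = list(preset = preset$name, time_s = t))
}

#' Simulate a full dehydration series
#'
#' `n_spectra` spectra at times `(k-1) * dt`, reproducible for a given seed.
#' Metadata records the preset name, the seed and the ground truth (target
#' HPI and analytic RAD gaps).
#'
#' @param preset A [sim_preset()].
#' @param seed Integer RNG seed.
#' @param sample_id Identifier (defaults to `"<preset>_s<seed>"`).
#' @param followup_T Follow-up day attached to the series.
#' @return A `dehydration_series` in instrument (raw) units, ready for
#'   [preprocess_series()] / [analyze_series()].
#' @export
simulate_series <- function(preset, seed = 1L,
                            sample_id = sprintf("%s_s%d", preset$name, seed),
                            followup_T = NA_real_) {
  stopifnot(inherits(preset, "sim_preset"))
  grid <- .canonical_grid()
  n <- preset$n_spectra
  times <- (seq_len(n) - 1) * preset$dt
  B <- .sim_basis(preset, grid)
  C <- .sim_coefs(preset, times)
  S <- B %*% C
  drift <- preset$drift_amp * sin(2 * pi * times / (n * preset$dt))
  S <- sweep(S, 2, drift, `+`)
  if (preset$noise_sd > 0) {
    S <- S + .with_seed(seed, function() {
      matrix(rnorm(length(S), 0, preset$noise_sd), nrow = nrow(S))
    })
  }
  S <- S * (1000 / grid)  # evanescent-wave penetration-depth weighting
  dehydration_series(
    grid, S, times = times, sample_id = sample_id, followup_T = followup_T,
    meta = list(preset = preset$name, seed = seed,
                ground_truth = preset$ground_truth))
}

#' Simulate a labelled cohort of dehydration series
#'
#' @param groups Named list mapping a group label to either a [sim_preset()]
#'   (with `n` given via `n_per_group`) or a list `list(preset = , n = )`.
#' @param seed Base seed; series `i` of the cohort uses `seed + i`.
#' @param n_per_group Default group size when a bare preset is given.
#' @return A list with elements `series` (list of `dehydration_series`) and
#'   `labels` (character vector of group labels, parallel to `series`).
#' @export
simulate_cohort <- function(groups, seed = 42L, n_per_group = 1L) {
  series <- list()
  labels <- character(0)
  i <- 0L
  for (label in names(groups)) {
    g <- groups[[label]]
    if (inherits(g, "sim_preset")) g <- list(preset = g, n = n_per_group)
    stopifnot(inherits(g$preset, "sim_preset"), g$n >= 1)
    for (k in seq_len(g$n)) {
      i <- i + 1L
      series[[i]] <- simulate_series(
        g$preset, seed = seed + i,
        sample_id = sprintf("%s_%02d", label, k))
      labels[i] <- label
    }
  }
  list(series = series, labels = labels)
}
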