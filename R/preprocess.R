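# Per-spectrum corrections applied before any peak-height measurement.
# Fixed order in the pipeline: canonical grid -> ATR correction -> rubberband
# baseline -> (optional) triglyceride subtraction. No normalization is applied
# on the quantitative path: every downstream quantity (RAD, HPI) is a ratio of
# peak heights of the same spectrum and therefore scale-invariant.

#' ATR configuration
#'
#' Parameters of the attenuated-total-reflection geometry. The evanescent-wave
#' penetration depth is `d_p(nu) = 1/(2 pi nu n1 sqrt(sin^2(theta) -
#' (n2/n1)^2))`, i.e. proportional to `1/nu`; the ATR correction compensates
#' this by scaling absorbance with `nu/nu_ref`.
#'
#' @param crystal_index Refractive index of the ATR crystal (default 4.0,
#'   germanium).
#' @param sample_index Refractive index of the sample (default 1.5, dried
#'   serum film).
#' @param incidence_deg Angle of incidence in degrees (default 45).
#' @param ref_wavenumber Reference wavenumber in cm^-1 at which the correction
#'   multiplier is exactly 1 (default 1000).
#' @return An `atr_config` object.
#' @export
atr_config <- function(crystal_index = 4.0, sample_index = 1.5,
                       incidence_deg = 45, ref_wavenumber = 1000) {
  theta <- incidence_deg * pi / 180
  if (sin(theta)^2 <= (sample_index / crystal_index)^2) {
    stop("no total internal reflection: sin^2(theta) must exceed (n2/n1)^2",
         call. = FALSE)
  }
  structure(list(crystal_index = crystal_index, sample_index = sample_index,
                 incidence_deg = incidence_deg,
                 ref_wavenumber = ref_wavenumber),
            class = "atr_config")
}

#' Evanescent-wave penetration depth
#'
#' @param wavenumber Wavenumbers, cm^-1.
#' @param cfg An [atr_config()].
#' @return Penetration depth in micrometres.
#' @examples
#' penetration_depth(1000, atr_config())  # 0.664 um for Ge/serum at 45 deg
#' @export
penetration_depth <- function(wavenumber, cfg = atr_config()) {
  theta <- cfg$incidence_deg * pi / 180
  lambda_um <- 1e4 / wavenumber
  lambda_um / (2 * pi * cfg$crystal_index *
                 sqrt(sin(theta)^2 -
                        (cfg$sample_index / cfg$crystal_index)^2))
}

.atr_multiplier <- function(wavenumber, cfg) wavenumber / cfg$ref_wavenumber

#' Correct the 1/nu penetration-depth dependence of ATR absorbance
#'
#' Multiplies the absorbance pointwise by `nu/nu_ref`, undoing the wavenumber
#' dependence of the effective path length. Applied at most once: a metadata
#' flag guards against re-application.
#'
#' @param s An `ir_spectrum` or `dehydration_series`.
#' @param cfg An [atr_config()].
#' @return The corrected object with `meta$atr_corrected = TRUE`.
#' @export
atr_correct <- function(s, cfg = atr_config()) {
  UseMethod("atr_correct")
}

#' @export
atr_correct.ir_spectrum <- function(s, cfg = atr_config()) {
  if (isTRUE(s$meta$atr_corrected)) {
    stop("spectrum is already ATR-corrected", call. = FALSE)
  }
  s$absorbance <- s$absorbance * .atr_multiplier(s$wavenumbers, cfg)
  s$meta$atr_corrected <- TRUE
  s
}

#' @export
atr_correct.dehydration_series <- function(s, cfg = atr_config()) {
  if (isTRUE(s$meta$atr_corrected)) {
    stop("series is already ATR-corrected", call. = FALSE)
  }
  s$absorbance <- s$absorbance * .atr_multiplier(s$wavenumbers, cfg)
  s$meta$atr_corrected <- TRUE
  s
}

# Lower convex hull baseline of one (x, y) polyline, evaluated on x.
.lower_hull_baseline <- function(x, y) {
  n <- length(x)
  h <- chull(x, y)
  # walk the hull cyclically from the leftmost to the rightmost vertex in
  # both directions; the lower chain is the one with the smaller mean height
  i_left <- which(h == which.min(x))[1]
  i_right <- which(h == which.max(x))[1]
  walk <- function(from, to, step) {
    idx <- from
    i <- from
    while (i != to) {
      i <- if (step > 0) (i %% length(h)) + 1L else ((i - 2L) %% length(h)) + 1L
      idx <- c(idx, i)
    }
    h[idx]
  }
  c1 <- walk(i_left, i_right, 1L)
  c2 <- walk(i_left, i_right, -1L)
  pick <- function(ch) {
    ch <- ch[order(x[ch])]
    approx(x[ch], y[ch], xout = x, rule = 2)$y
  }
  b1 <- pick(c1)
  b2 <- pick(c2)
  if (mean(b1) <= mean(b2)) b1 else b2
}

#' Rubberband (lower convex hull) baseline correction
#'
#' Subtracts the lower convex hull of the `(wavenumber, absorbance)` polyline.
#' The result is non-negative everywhere, zero at the hull contact points, and
#' the operation is idempotent. An all-equal (or affine) spectrum maps to all
#' zeros.
#'
#' @param s An `ir_spectrum` or `dehydration_series`.
#' @return The baseline-corrected object with `meta$baseline = "rubberband"`.
#' @export
baseline_rubberband <- function(s) {
  UseMethod("baseline_rubberband")
}

#' @export
baseline_rubberband.ir_spectrum <- function(s) {
  if (length(s$wavenumbers) < 3) stop("need >= 3 points", call. = FALSE)
  b <- .lower_hull_baseline(s$wavenumbers, s$absorbance)
  s$absorbance <- pmax(s$absorbance - b, 0)
  s$meta$baseline <- "rubberband"
  s
}

#' @export
baseline_rubberband.dehydration_series <- function(s) {
  if (length(s$wavenumbers) < 3) stop("need >= 3 points", call. = FALSE)
  x <- s$wavenumbers
  s$absorbance <- apply(s$absorbance, 2, function(y) {
    pmax(y - .lower_hull_baseline(x, y), 0)
  })
  s$meta$baseline <- "rubberband"
  s
}

#' Asymmetric least squares (Whittaker) baseline correction
#'
#' Alternative to the rubberband default: iteratively reweighted penalized
#' least squares with asymmetry parameter `p` and smoothness `lambda`
#' (Eilers-style). Useful when broad real bands should not be cut into.
#'
#' @param s An `ir_spectrum`.
#' @param lambda Smoothness penalty (default 1e5).
#' @param p Asymmetry weight for points above the baseline (default 0.01).
#' @param iterations Number of reweighting iterations (default 10).
#' @return The baseline-corrected spectrum (not clipped to be non-negative).
#' @export
baseline_als <- function(s, lambda = 1e5, p = 0.01, iterations = 10) {
  stopifnot(inherits(s, "ir_spectrum"))
  y <- s$absorbance
  m <- length(y)
  # second-difference penalty, dense banded solve via base R
  D <- diff(diag(m), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(iterations)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  s$absorbance <- y - z
  s$meta$baseline <- "als"
  s
}

#' Synthetic unit-amplitude triglyceride reference spectrum
#'
#' Gaussian bands at 2931, 2855, 1737 and 1456 cm^-1 with amplitude ratios
#' 1.0 : 0.55 : 0.9 : 0.35 and sigma = 10 cm^-1, rescaled so the peak height
#' in the 1737 +/- 15 cm^-1 ester carbonyl anchor band is exactly 1. This is a
#' synthetic stand-in for a measured triglyceride standard; real deployments
#' should supply their own measured reference via [tg_reference()].
#'
#' @param wavenumbers Grid to evaluate on (default the canonical grid).
#' @return A `tg_reference` object (fields `spectrum`, `anchor_center`,
#'   `anchor_half_width`).
#' @export
tg_reference_synthetic <- function(wavenumbers = .canonical_grid()) {
  centers <- c(2931, 2855, 1737, 1456)
  amps <- c(1.0, 0.55, 0.9, 0.35)
  y <- rowSums(vapply(seq_along(centers), function(i) {
    amps[i] * exp(-(wavenumbers - centers[i])^2 / (2 * 10^2))
  }, numeric(length(wavenumbers))))
  anchor <- abs(wavenumbers - 1737) <= 15
  y <- y / max(y[anchor])
  tg_reference(ir_spectrum(wavenumbers, y, meta = list(synthetic = TRUE)))
}

#' Construct a triglyceride reference from a measured spectrum
#'
#' @param spectrum An `ir_spectrum` of a triglyceride standard; it is rescaled
#'   so its anchor-band peak height equals 1 and must be non-negative.
#' @param anchor_center,anchor_half_width Anchor band (ester nu(C=O)),
#'   default 1737 +/- 15 cm^-1.
#' @return A `tg_reference` object.
#' @export
tg_reference <- function(spectrum, anchor_center = 1737,
                         anchor_half_width = 15) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (any(spectrum$absorbance < -1e-9)) {
    stop("triglyceride reference must be non-negative", call. = FALSE)
  }
  win <- abs(spectrum$wavenumbers - anchor_center) <= anchor_half_width
  pk <- max(spectrum$absorbance[win])
  if (pk <= 0) stop("reference has no signal in the anchor band",
                    call. = FALSE)
  spectrum$absorbance <- spectrum$absorbance / pk
  structure(list(spectrum = spectrum, anchor_center = anchor_center,
                 anchor_half_width = anchor_half_width),
            class = "tg_reference")
}

# LS design for the lipid amount: the band shape plus a quartic local
# background over a window somewhat wider than the anchor band (+/- 25 vs
# +/- 15 cm^-1). The extra width decorrelates the narrow band from the
# polynomial, which would otherwise either track the band itself (narrow
# window, high degree) or fail to absorb the curvature of overlapping broad
# features such as the liquid-phase water bending tail (low degree).
.tg_design <- function(ref, wavenumbers, fit_half_width = 25, degree = 4) {
  win <- which(abs(wavenumbers - ref$anchor_center) <= fit_half_width)
  r <- approx(ref$spectrum$wavenumbers, ref$spectrum$absorbance,
              xout = wavenumbers[win], rule = 2)$y
  x <- (wavenumbers[win] - ref$anchor_center) / fit_half_width
  X <- cbind(r, outer(x, 0:degree, `^`))
  list(win = win, X = X, proj = solve(crossprod(X), t(X)))
}

#' Subtract triglyceride interference from a baseline-corrected spectrum
#'
#' Estimates the lipid amount `alpha` in the ester carbonyl anchor band
#' (1737 cm^-1, the only strong serum band free of protein overlap) and
#' subtracts `alpha` times the unit-amplitude reference. Two estimators:
#'
#' * `"ls"` (default): ordinary least squares of the spectrum on the reference
#'   over the anchor window with a quadratic local background. Exact for
#'   noiseless multiples of the reference and unbiased under zero-mean noise.
#' * `"peak"`: the anchor-band peak height of the spectrum divided by that of
#'   the reference (which is 1 by construction).
#'
#' A negative estimate is clamped to 0 with a warning (no lipid signal); a
#' warning is also raised when any corrected value drops below -0.02 AU.
#'
#' @param s An `ir_spectrum` or `dehydration_series`, baseline-corrected and
#'   on (or interpolable to) the reference grid.
#' @param ref A [tg_reference()] (default the synthetic fixture).
#' @param alpha_method `"ls"` or `"peak"`.
#' @return The corrected object; `meta$tg_alpha` records the estimate(s).
#' @export
tg_correct <- function(s, ref = tg_reference_synthetic(),
                       alpha_method = c("ls", "peak")) {
  UseMethod("tg_correct")
}

.tg_alpha <- function(y, wavenumbers, ref, design, alpha_method) {
  if (alpha_method == "peak") {
    max(y[design$win])
  } else {
    as.numeric(design$proj %*% y[design$win])[1]
  }
}

.tg_apply <- function(y, wavenumbers, ref, alpha) {
  r <- approx(ref$spectrum$wavenumbers, ref$spectrum$absorbance,
              xout = wavenumbers, rule = 2)$y
  y - alpha * r
}

#' @export
tg_correct.ir_spectrum <- function(s, ref = tg_reference_synthetic(),
                                   alpha_method = c("ls", "peak")) {
  alpha_method <- match.arg(alpha_method)
  design <- .tg_design(ref, s$wavenumbers)
  alpha <- .tg_alpha(s$absorbance, s$wavenumbers, ref, design, alpha_method)
  if (alpha < 0) {
    # numerically-zero negatives are clamped silently
    if (alpha < -1e-4) {
      warning("negative triglyceride estimate clamped to 0 (no lipid signal)")
    }
    alpha <- 0
  }
  out <- .tg_apply(s$absorbance, s$wavenumbers, ref, alpha)
  if (any(out < -0.02)) {
    warning("triglyceride correction produced values below -0.02 AU")
  }
  s$absorbance <- out
  s$meta$tg_alpha <- alpha
  s$meta$tg_corrected <- TRUE
  s
}

#' @export
tg_correct.dehydration_series <- function(s, ref = tg_reference_synthetic(),
                                          alpha_method = c("ls", "peak")) {
  alpha_method <- match.arg(alpha_method)
  design <- .tg_design(ref, s$wavenumbers)
  alphas <- if (alpha_method == "peak") {
    apply(s$absorbance[design$win, , drop = FALSE], 2, max)
  } else {
    as.numeric((design$proj %*% s$absorbance[design$win, , drop = FALSE])[1, ])
  }
  n_neg <- sum(alphas < -1e-4)
  if (n_neg > 0) {
    warning(sprintf(
      "negative triglyceride estimate clamped to 0 in %d spectra", n_neg))
  }
  alphas <- pmax(alphas, 0)
  r <- approx(ref$spectrum$wavenumbers, ref$spectrum$absorbance,
              xout = s$wavenumbers, rule = 2)$y
  s$absorbance <- s$absorbance - outer(r, alphas)
  if (any(s$absorbance < -0.02)) {
    warning("triglyceride correction produced values below -0.02 AU")
  }
  s$meta$tg_alpha <- alphas
  s$meta$tg_corrected <- TRUE
  s
}

#' Optional Savitzky-Golay smoothing
#'
#' Off by default; uses a polynomial least-squares convolution filter.
#'
#' @param s An `ir_spectrum` or `dehydration_series`.
#' @param window Odd filter length (default 9).
#' @param order Polynomial order (default 3).
#' @return The smoothed object.
#' @export
smooth_sg <- function(s, window = 9, order = 3) {
  stopifnot(window %% 2 == 1, order < window)
  half <- (window - 1) / 2
  z <- outer(-half:half, 0:order, `^`)
  coef <- solve(crossprod(z), t(z))[1, ]
  sm <- function(y) {
    n <- length(y)
    pad <- c(rev(y[2:(half + 1)]), y, rev(y[(n - half):(n - 1)]))
    as.numeric(stats::filter(pad, rev(coef), sides = 2))[(half + 1):(half + n)]
  }
  if (inherits(s, "dehydration_series")) {
    s$absorbance <- apply(s$absorbance, 2, sm)
  } else {
    s$absorbance <- sm(s$absorbance)
  }
  s
}

#' Run the full preprocessing chain on a series
#'
#' Order: interpolate to the canonical grid, ATR-correct, rubberband (or ALS)
#' baseline, then optionally subtract the triglyceride reference. RAD-type
#' quantities are ratios of peak heights of the same spectrum, so no
#' normalization step is part of the quantitative chain.
#'
#' @param series A raw `dehydration_series`.
#' @param tg Logical: apply triglyceride subtraction (needed for the Hp, Alb
#'   and Gly indices and for the HPI).
#' @param config Optional `preprocess` config block (see [default_config()]).
#' @return The preprocessed series.
#' @export
preprocess_series <- function(series, tg = FALSE, config = NULL) {
  cfg <- default_config()$preprocess
  if (!is.null(config)) cfg <- modifyList(cfg, config)
  s <- to_canonical_grid(series)
  acfg <- atr_config(cfg$atr$n_crystal, cfg$atr$n_sample, cfg$atr$angle_deg,
                     cfg$atr$ref_wavenumber)
  s <- atr_correct(s, acfg)
  if (isTRUE(cfg$smoothing$enabled)) {
    s <- smooth_sg(s, cfg$smoothing$window, cfg$smoothing$order)
  }
  if (identical(cfg$baseline$method, "als")) {
    ab <- apply(s$absorbance, 2, function(y) {
      baseline_als(ir_spectrum(s$wavenumbers, y))$absorbance
    })
    s$absorbance <- ab
    s$meta$baseline <- "als"
  } else {
    s <- baseline_rubberband(s)
  }
  if (isTRUE(tg) && isTRUE(cfg$tg$enabled)) {
    ref <- if (!is.null(cfg$tg$reference_path)) {
      tg_reference(.read_jcamp_file(cfg$tg$reference_path))
    } else {
      tg_reference_synthetic(s$wavenumbers)
    }
    s <- tg_correct(s, ref, alpha_method = cfg$tg$alpha_method)
  }
  s
}
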