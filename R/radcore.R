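# RAD temporal profiles, RAD gaps and the serum hydrophobicity index.

#' Define a spectral index as a target/reference band pair
#'
#' @param name Index name.
#' @param nu1 [band_def()] of the target band (PH1).
#' @param nu2 [band_def()] of the reference band (PH2).
#' @param tg_corrected Logical: does this index require triglyceride
#'   subtraction before measurement?
#' @return A `spectral_index` object.
#' @export
spectral_index <- function(name, nu1, nu2, tg_corrected = FALSE) {
  stopifnot(inherits(nu1, "band_def"), inherits(nu2, "band_def"))
  if (nu1$center == nu2$center) {
    stop("target and reference bands must differ", call. = FALSE)
  }
  structure(list(name = name, nu1 = nu1, nu2 = nu2,
                 tg_corrected = isTRUE(tg_corrected)),
            class = "spectral_index")
}

#' The five canonical serum spectral indices
#'
#' Band pairs (target nu1 / reference nu2, cm^-1) and triglyceride-correction
#' flags:
#' \describe{
#'   \item{Hp}{2930 / 2960, TG-corrected. Hydrophobicity: CH2 antisymmetric
#'     stretch (glycan methylenes) against the protein CH3 stretch.}
#'   \item{Hph}{1546 / 1650. Hydrophilicity: amide II against amide I.}
#'   \item{Alb}{1400 / 1450, TG-corrected. Albumin: carboxylate bend against
#'     CH2 scissoring.}
#'   \item{Lact}{1121 / 1171. Lactate delta(C-O-H) against the serine C-O-H
#'     reference.}
#'   \item{Gly}{1030 / 1171, TG-corrected. IgG glycosylation: glycosidic
#'     C-O-C against the same serine reference.}
#' }
#' Any center, half-width or flag can be overridden through the `indices:`
#' config block.
#'
#' @param overrides Optional named list of per-index overrides, e.g.
#'   `list(Hp = list(nu1 = 2929, half_width = 6))`.
#' @return Named list of five [spectral_index()] objects.
#' @export
canonical_indices <- function(overrides = NULL) {
  tab <- list(
    Hp   = list(nu1 = 2930, nu2 = 2960, tg = TRUE),
    Hph  = list(nu1 = 1546, nu2 = 1650, tg = FALSE),
    Alb  = list(nu1 = 1400, nu2 = 1450, tg = TRUE),
    Lact = list(nu1 = 1121, nu2 = 1171, tg = FALSE),
    Gly  = list(nu1 = 1030, nu2 = 1171, tg = TRUE)
  )
  out <- lapply(names(tab), function(nm) {
    e <- tab[[nm]]
    hw <- 8
    if (!is.null(overrides[[nm]])) {
      o <- overrides[[nm]]
      if (!is.null(o$nu1)) e$nu1 <- o$nu1
      if (!is.null(o$nu2)) e$nu2 <- o$nu2
      if (!is.null(o$tg_corrected)) e$tg <- o$tg_corrected
      if (!is.null(o$half_width)) hw <- o$half_width
    }
    spectral_index(nm,
                   band_def(paste0(nm, "_nu1"), e$nu1, hw),
                   band_def(paste0(nm, "_nu2"), e$nu2, hw),
                   tg_corrected = e$tg)
  })
  names(out) <- names(tab)
  out
}

#' Relative absorption difference of two peak heights
#'
#' `RAD = (PH1 - PH2) / PH1`, the relative change of the target band height
#' against its reference at one dehydration time point.
#'
#' @param ph1 Target peak height (AU), non-zero.
#' @param ph2 Reference peak height (AU).
#' @return `(ph1 - ph2) / ph1`.
#' @examples
#' rad(2, 1)   # 0.5
#' rad(1, 2)   # -1
#' @export
rad <- function(ph1, ph2) {
  if (any(ph1 == 0)) {
    stop("RAD is undefined for a zero target peak height", call. = FALSE)
  }
  (ph1 - ph2) / ph1
}

#' Temporal RAD profile of one index over a dehydration series
#'
#' Computes `RAD(nu1, nu2, t)` at every acquisition time. Time points where
#' the target height PH1 is at or below 1e-6 AU are recorded as missing
#' rather than raising an error; a quality warning is attached when more than
#' 20% of points are missing.
#'
#' @param series A `dehydration_series`, preprocessed consistently with
#'   `idx$tg_corrected` (see [preprocess_series()]).
#' @param idx A [spectral_index()].
#' @param mode Peak-height mode, see [peak_height()].
#' @return A `rad_profile` object: `index`, `times`, `values` (NA = missing),
#'   `quality_warning`.
#' @export
rad_profile <- function(series, idx, mode = "global") {
  stopifnot(inherits(series, "dehydration_series"),
            inherits(idx, "spectral_index"))
  m1 <- .peak_height_cols(series$wavenumbers, series$absorbance, idx$nu1, mode)
  m2 <- .peak_height_cols(series$wavenumbers, series$absorbance, idx$nu2, mode)
  ph1 <- m1$height
  vals <- rep(NA_real_, length(ph1))
  ok <- ph1 > 1e-6
  vals[ok] <- (ph1[ok] - m2$height[ok]) / ph1[ok]
  frac_missing <- mean(!ok)
  qw <- NULL
  if (frac_missing > 0.2) {
    qw <- sprintf("%.0f%% of RAD points missing (PH1 <= 1e-6 AU)",
                  100 * frac_missing)
    warning(qw, call. = FALSE)
  }
  structure(list(index = idx, times = series$times, values = vals,
                 quality_warning = qw),
            class = "rad_profile")
}

#' RAD gap: initial-phase minus final-phase mean RAD
#'
#' `Psi = mean(values[1:window]) - mean(values[(n-window+1):n])`, the mean RAD
#' of the first `window` acquisitions (liquid phase) minus that of the final
#' `window` acquisitions (dried film). Missing points are excluded from the
#' means; each mean must rest on at least `window/2` valid points.
#'
#' @param profile A [rad_profile()] (or plain numeric vector of RAD values).
#' @param window Number of spectra averaged at each end (default 100). The
#'   profile must contain at least `2 * window` points; shorter runs require
#'   an explicit smaller window.
#' @param sign_convention `"initial_minus_final"` (default) or
#'   `"final_minus_initial"`.
#' @return The gap Psi (dimensionless scalar).
#' @export
rad_gap <- function(profile, window = 100,
                    sign_convention = c("initial_minus_final",
                                        "final_minus_initial")) {
  sign_convention <- match.arg(sign_convention)
  v <- if (inherits(profile, "rad_profile")) profile$values else
    as.numeric(profile)
  n <- length(v)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (n < 2 * window) {
    stop(sprintf(
      "profile has %d points but 2*window = %d are required; pass a smaller window",
      n, 2 * window), call. = FALSE)
  }
  first <- v[seq_len(window)]
  last <- v[seq.int(n - window + 1L, n)]
  if (sum(is.finite(first)) < window / 2 || sum(is.finite(last)) < window / 2) {
    stop("insufficient valid RAD points in the averaging windows",
         call. = FALSE)
  }
  g <- mean(first, na.rm = TRUE) - mean(last, na.rm = TRUE)
  if (sign_convention == "final_minus_initial") -g else g
}

#' RAD gaps for the five canonical indices of one series
#'
#' Preprocesses the raw series twice (with and without triglyceride
#' subtraction), computes each index's RAD profile on the appropriate version
#' and returns the gap set.
#'
#' @param series A raw `dehydration_series`.
#' @param window Averaging window, see [rad_gap()].
#' @param indices Named list from [canonical_indices()].
#' @param config Optional full config (see [default_config()]).
#' @return A `rad_gap_set`: `followup_T`, `gaps` (named list of the five Psi),
#'   `window`.
#' @export
rad_gap_set <- function(series, window = 100, indices = canonical_indices(),
                        config = NULL) {
  pp <- .preprocess_both(series, indices, config)
  sign_conv <- .cfg_gap_sign(config)
  gaps <- lapply(indices, function(idx) {
    src <- if (idx$tg_corrected) pp$tg else pp$base
    rad_gap(rad_profile(src, idx), window = window,
            sign_convention = sign_conv)
  })
  structure(list(followup_T = series$followup_T, gaps = gaps,
                 window = window),
            class = "rad_gap_set")
}

.preprocess_both <- function(series, indices, config) {
  pcfg <- if (!is.null(config$preprocess)) config$preprocess else NULL
  base <- preprocess_series(series, tg = FALSE, config = pcfg)
  need_tg <- any(vapply(indices, function(i) i$tg_corrected, logical(1)))
  tg <- if (need_tg) {
    ref <- tg_reference_synthetic(base$wavenumbers)
    am <- if (!is.null(pcfg$tg$alpha_method)) pcfg$tg$alpha_method else "ls"
    tg_correct(base, ref, alpha_method = am)
  } else {
    base
  }
  list(base = base, tg = tg)
}

.cfg_gap_sign <- function(config) {
  sc <- config$gap$sign_convention
  if (is.null(sc)) "initial_minus_final" else sc
}

#' Serum hydrophobicity index of the dried film
#'
#' `HPI = PH1(nu_as(CH2), ~2930 cm^-1) / PH2(nu_as(CH3), ~2960 cm^-1)` on the
#' lipid-corrected dried film: the per-spectrum height ratio is averaged over
#' the final `window` acquisitions. The methylene stretch grows with the
#' glycan load of IgG, the methyl stretch tracks total protein, so the ratio
#' reads out serum hydrophobicity changes driven by IgG glycosylation.
#'
#' @param series A triglyceride-corrected, preprocessed `dehydration_series`.
#' @param window Number of terminal spectra averaged (default 100).
#' @param nu1,nu2 Band definitions (defaults 2930 and 2960 cm^-1, half-width
#'   8).
#' @return An `hpi_result`: `value`, `n_averaged`.
#' @export
hpi <- function(series, window = 100,
                nu1 = band_def("ch2_as", 2930), nu2 = band_def("ch3_as", 2960)) {
  stopifnot(inherits(series, "dehydration_series"))
  n <- ncol(series$absorbance)
  if (n < window) stop("series shorter than the HPI window", call. = FALSE)
  sel <- seq.int(n - window + 1L, n)
  sub <- series
  sub$absorbance <- series$absorbance[, sel, drop = FALSE]
  sub$times <- series$times[sel]
  m1 <- .peak_height_cols(sub$wavenumbers, sub$absorbance, nu1)
  m2 <- .peak_height_cols(sub$wavenumbers, sub$absorbance, nu2)
  if (any(m2$height <= 1e-6)) {
    stop("reference CH3 peak height <= 1e-6 AU in the terminal window",
         call. = FALSE)
  }
  structure(list(value = mean(m1$height / m2$height), n_averaged = window),
            class = "hpi_result")
}

#' @export
print.hpi_result <- function(x, ...) {
  cat(sprintf("HPI = %.4f (mean of %d dried-film spectra)\n",
              x$value, x$n_averaged))
  invisible(x)
}
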