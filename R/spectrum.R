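#' @importFrom stats approx median quantile rnorm sd wilcox.test cor.test setNames
#' @importFrom grDevices chull
#' @importFrom utils head tail modifyList
NULL

# Canonical analysis grid: ascending, linear, 2 cm^-1 over 650-3998 cm^-1
# (instrument resolution is 4 cm^-1, so 2 cm^-1 sampling is comfortable).
.canonical_grid <- function() seq(650, 3998, by = 2)

#' Single infrared absorbance spectrum
#'
#' A spectrum is an absorbance trace on a strictly ascending wavenumber grid.
#' Descending input grids are reversed (with the absorbance co-reversed) so
#' that all downstream band windows are index-stable.
#'
#' @param wavenumbers Numeric vector, cm^-1. Strictly monotone; descending
#'   input is reversed on construction.
#' @param absorbance Numeric vector of the same length, absorbance units (AU).
#' @param meta Named list of metadata strings (sample id, acquisition time,
#'   processing flags).
#' @return An object of class `ir_spectrum` with elements `wavenumbers`,
#'   `absorbance` and `meta`.
#' @examples
#' s <- ir_spectrum(seq(1000, 1100, 2), rep(0.1, 51))
#' @export
ir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    stop("non-finite values in spectrum", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (any(d <= 0)) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.0f-%.0f cm^-1, max %.4g AU\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              max(x$absorbance)))
  invisible(x)
}

#' Time-ordered dehydration series of one serum droplet
#'
#' All spectra of a run share one grid, so the series stores absorbance as a
#' wavenumber-by-time matrix. Times are seconds since the first acquisition;
#' when absent they default to the instrument cadence `k * 0.791` s.
#'
#' @param wavenumbers Ascending numeric grid, cm^-1 (descending is reversed,
#'   with rows of `absorbance` co-reversed).
#' @param absorbance Numeric matrix, `length(wavenumbers)` rows, one column
#'   per time point (>= 2 columns).
#' @param times Strictly increasing numeric vector of acquisition times in
#'   seconds, one per column; `NULL` synthesizes `(k-1) * 0.791`.
#' @param sample_id Sample identifier string.
#' @param followup_T Follow-up time of the sample in days since diagnosis.
#' @param meta Named list of metadata.
#' @return An object of class `dehydration_series`.
#' @examples
#' m <- matrix(runif(20), nrow = 10)
#' ds <- dehydration_series(seq(1000, 1018, 2), m)
#' @export
dehydration_series <- function(wavenumbers, absorbance, times = NULL,
                               sample_id = "sample", followup_T = NA_real_,
                               meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumbers)) {
    stop("absorbance must have one row per wavenumber", call. = FALSE)
  }
  if (ncol(absorbance) < 2) {
    stop("a dehydration series needs at least 2 time points", call. = FALSE)
  }
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance))) {
    stop("non-finite values in series", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
  } else if (any(d <= 0)) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  if (is.null(times)) {
    times <- (seq_len(ncol(absorbance)) - 1) * 0.791
  }
  times <- as.numeric(times)
  if (length(times) != ncol(absorbance)) {
    stop("times must have one entry per spectrum", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 times = times, sample_id = sample_id,
                 followup_T = followup_T, meta = meta),
            class = "dehydration_series")
}

#' @export
print.dehydration_series <- function(x, ...) {
  cat(sprintf(
    "<dehydration_series> '%s': %d spectra x %d points, t = %.2f-%.2f s\n",
    x$sample_id, ncol(x$absorbance), length(x$wavenumbers),
    min(x$times), max(x$times)))
  invisible(x)
}

#' Number of spectra in a series
#' @param series A `dehydration_series`.
#' @return Integer count of time points.
#' @export
n_spectra <- function(series) {
  stopifnot(inherits(series, "dehydration_series"))
  ncol(series$absorbance)
}

#' Extract one spectrum from a series
#' @param series A `dehydration_series`.
#' @param k Time index (1-based).
#' @return An `ir_spectrum` carrying the series metadata plus the time point.
#' @export
get_spectrum <- function(series, k) {
  stopifnot(inherits(series, "dehydration_series"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(series$absorbance)) stop("time index out of range")
  meta <- series$meta
  meta$time_s <- series$times[k]
  meta$time_index <- k
  ir_spectrum(series$wavenumbers, series$absorbance[, k], meta)
}

#' Interpolate a series onto the canonical analysis grid
#'
#' The quantitative pipeline runs on one fixed grid (ascending, 2 cm^-1 over
#' 650-3998 cm^-1) so that band windows are index-stable. Input grids must
#' cover at least 900-3100 cm^-1; within the canonical range but outside the
#' input range absorbance is extrapolated as the nearest edge value.
#'
#' @param series A `dehydration_series`.
#' @return The series linearly interpolated onto the canonical grid (returned
#'   unchanged if already on it).
#' @export
to_canonical_grid <- function(series) {
  stopifnot(inherits(series, "dehydration_series"))
  grid <- .canonical_grid()
  wn <- series$wavenumbers
  if (length(wn) == length(grid) && isTRUE(all.equal(wn, grid))) {
    return(series)
  }
  if (min(wn) > 900 || max(wn) < 3100) {
    stop(sprintf(
      "wavenumber range %.0f-%.0f cm^-1 does not cover 900-3100 cm^-1",
      min(wn), max(wn)), call. = FALSE)
  }
  ab <- apply(series$absorbance, 2, function(y) {
    approx(wn, y, xout = grid, rule = 2)$y
  })
  dehydration_series(grid, ab, series$times, series$sample_id,
                     series$followup_T, series$meta)
}
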