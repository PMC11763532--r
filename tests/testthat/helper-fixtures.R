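# Shared fixtures: all built in code at test time.

grid_1k <- function(from = 900, to = 3200, by = 2) seq(from, to, by = by)

# Gaussian band on an arbitrary baseline function
gauss <- function(x, center, sigma = 10, amp = 1) {
  amp * exp(-(x - center)^2 / (2 * sigma^2))
}

gaussian_spectrum <- function(center = 1500, sigma = 10, amp = 1,
                              grid = grid_1k(), baseline = 0) {
  ir_spectrum(grid, gauss(grid, center, sigma, amp) + baseline)
}

# A small constant-in-time series: one spectrum replicated n times
constant_series <- function(spec, n = 10) {
  dehydration_series(spec$wavenumbers,
                     matrix(spec$absorbance, ncol = n,
                            nrow = length(spec$absorbance)),
                     times = (seq_len(n) - 1) * 0.791)
}

# Fast preset for tests that do not need the full 758-frame default: the
# water-decay sigmoid is compressed so the film is dry before the terminal
# averaging window (liquid for the first 100 frames, dried from frame ~115).
small_preset <- function(name = "healthy", n_spectra = 220,
                         water_decay_mid = 86, water_decay_rate = 0.6, ...) {
  sim_preset(name, n_spectra = n_spectra, water_decay_mid = water_decay_mid,
             water_decay_rate = water_decay_rate, ...)
}

# Independent Mann-Whitney oracle: full enumeration of group labelings.
# U convention: number of (x, y) pairs with x > y. Two-sided p = fraction of
# labelings whose U is at least as extreme (|U - mn/2| >= observed).
mw_enumerate <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, `>`))
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  center <- m * n / 2
  p <- mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
  list(U = u_obs, p = p)
}

# Brute-force lower convex hull baseline on a dense evaluation: for each
# point, the maximum over all chords lying below the curve. O(n^2), used only
# on small grids as an independent oracle for the rubberband correction.
brute_lower_hull <- function(x, y) {
  n <- length(x)
  b <- rep(-Inf, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      yy <- y[i] + (y[j] - y[i]) * (x - x[i]) / (x[j] - x[i])
      if (all(yy <= y + 1e-12)) b <- pmax(b, yy)
    }
  }
  pmin(b, y)
}

# Minimal JCAMP-DX writer for reader tests (AFFN, X++(Y..Y), one Y per line)
write_jcamp <- function(path, wavenumbers, absorbance, xunits = "1/CM",
                        time = NULL) {
  lines <- c(
    "##TITLE=synthetic test spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    sprintf("##XUNITS=%s", xunits),
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.6f", wavenumbers[1]),
    sprintf("##LASTX=%.6f", wavenumbers[length(wavenumbers)]),
    sprintf("##NPOINTS=%d", length(wavenumbers)))
  if (!is.null(time)) lines <- c(lines, sprintf("##TIME=%.3f", time))
  lines <- c(lines, "##XYDATA=(X++(Y..Y))",
             sprintf("%.6f %.8f", wavenumbers, absorbance),
             "##END=")
  writeLines(lines, path)
  path
}
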