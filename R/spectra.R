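#' Subtract a buffer baseline from a sample spectrum
#'
#' Pointwise `sample - buffer`; the two scans must share an identical
#' wavelength grid (no interpolation is performed).
#'
#' @param sample,buffer `"xy_spectrum"` objects on the same grid.
#' @return the baseline-subtracted `"xy_spectrum"`.
#' @export
subtract_baseline <- function(sample, buffer) {
  stopifnot(inherits(sample, "xy_spectrum"), inherits(buffer, "xy_spectrum"))
  if (length(sample$x) != length(buffer$x) ||
      any(sample$x != buffer$x))
    stop("sample and buffer wavelength grids differ")
  sample$y <- sample$y - buffer$y
  sample
}

#' Convert CD millidegrees to molar ellipticity
#'
#' \deqn{[\theta] = \theta_{mdeg} / (10\, c\, l)}
#' with `c` the molar concentration and `l` the pathlength in cm, giving
#' deg cm\eqn{^2} dmol\eqn{^{-1}}. Optionally divides further by
#' (`n_residues` - 1) for mean-residue ellipticity.
#'
#' @param spec buffer-subtracted `"xy_spectrum"` in mdeg.
#' @param conc_M molar protein concentration (> 0).
#' @param path_cm pathlength in cm (> 0).
#' @param mean_residue divide by the number of peptide bonds.
#' @param n_residues required when `mean_residue = TRUE`.
#' @return `"xy_spectrum"` in deg cm^2/dmol.
#' @export
to_molar_ellipticity <- function(spec, conc_M, path_cm,
                                 mean_residue = FALSE, n_residues = NULL) {
  stopifnot(inherits(spec, "xy_spectrum"))
  if (conc_M <= 0 || path_cm <= 0)
    stop("concentration and pathlength must be positive")
  spec$y <- spec$y / (10 * conc_M * path_cm)
  if (mean_residue) {
    if (is.null(n_residues) || n_residues < 2L)
      stop("mean-residue conversion needs n_residues >= 2")
    spec$y <- spec$y / (n_residues - 1L)
  }
  spec$meta$y_unit <- if (mean_residue) "deg.cm2/dmol/residue"
  else "deg.cm2/dmol"
  spec
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares local-polynomial smoothing on a uniform grid: each point
#' is replaced by the center value of the degree-`polyorder` polynomial
#' fit over the surrounding `window` points (edges by polynomial
#' extension of the terminal windows). Reproduces any polynomial of
#' degree `<= polyorder` exactly.
#'
#' @param spec an `"xy_spectrum"` with uniform x spacing.
#' @param window odd window length in points (default 11).
#' @param polyorder polynomial order (default 3; `< window - 1`).
#' @return the smoothed `"xy_spectrum"`.
#' @export
savgol_smooth <- function(spec, window = 11L, polyorder = 3L) {
  stopifnot(inherits(spec, "xy_spectrum"))
  dx <- diff(spec$x)
  if (max(abs(dx - dx[1L])) > 1e-8 * abs(dx[1L]))
    stop("Savitzky-Golay smoothing requires a uniform wavelength grid")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > length(spec$x)) stop("window exceeds spectrum length")
  if (polyorder >= window - 1L)
    stop("polyorder must be at most window - 2")
  spec$y <- as.numeric(signal::sgolayfilt(spec$y, p = polyorder,
                                          n = window))
  spec
}

#' Locate an emission peak maximum by polynomial fitting
#'
#' Fits a least-squares polynomial of the given degree (default 6, the
#' common convention for fluorescence emission maxima) over the whole
#' spectrum and locates the maximum among the real critical points inside
#' the scanned window, refined against a dense evaluation grid. If the
#' polynomial attains its maximum on the window boundary the result is
#' flagged `edge = TRUE` (monotone data carry no interior peak).
#'
#' @param spec an `"xy_spectrum"`.
#' @param degree polynomial degree (default 6); needs
#'   `length(x) >= degree + 2`.
#' @return list of class `"peak_max"`: `wavelength` (nm), `degree`,
#'   `rmse`, `edge`, `coefficients` (in the centered variable).
#' @export
polyfit_peak_max <- function(spec, degree = 6L) {
  stopifnot(inherits(spec, "xy_spectrum"))
  x <- spec$x; y <- spec$y
  if (length(x) < degree + 2L)
    stop("need at least degree + 2 points")
  # center/scale x for conditioning; fit raw powers of the scaled variable
  x0 <- mean(x); sx <- max(x) - min(x)
  u <- (x - x0) / sx
  X <- outer(u, 0:degree, `^`)
  cf <- qr.solve(X, y)
  pred <- as.vector(X %*% cf)
  rmse <- sqrt(mean((y - pred)^2))
  poly_eval <- function(uu) {
    sapply(uu, function(v) sum(cf * v^(0:degree)))
  }
  # critical points: roots of the derivative
  dcf <- cf[-1L] * seq_len(degree)
  crit <- polyroot(dcf)
  crit <- Re(crit[abs(Im(crit)) < 1e-8])
  crit <- crit[crit > min(u) & crit < max(u)]
  # dense-grid fallback/refinement
  ug <- seq(min(u), max(u), length.out = 2001L)
  cand <- c(crit, ug[which.max(poly_eval(ug))])
  best <- cand[which.max(poly_eval(cand))]
  vals_edge <- poly_eval(range(u))
  edge <- max(vals_edge) >= poly_eval(best) - 1e-12 * max(abs(y), 1)
  wl <- best * sx + x0
  structure(list(wavelength = wl, degree = degree, rmse = rmse,
                 edge = edge, coefficients = cf),
            class = "peak_max")
}

#' @export
print.peak_max <- function(x, ...) {
  cat(sprintf("Peak maximum: %.2f nm (degree-%d polynomial, rmse %.3g)%s\n",
              x$wavelength, x$degree, x$rmse,
              if (x$edge) "  [edge maximum: no interior peak]" else ""))
  invisible(x)
}

#' Pointwise average of replicate spectra
#'
#' Replicate scans (e.g. fluorescence triplicates) are averaged pointwise
#' before any fitting; all spectra must share the grid.
#'
#' @param specs list of `"xy_spectrum"` objects on identical grids.
#' @return an `"xy_spectrum"`.
#' @export
average_spectra <- function(specs) {
  stopifnot(length(specs) >= 1L)
  x <- specs[[1L]]$x
  for (s in specs)
    if (length(s$x) != length(x) || any(s$x != x))
      stop("replicate spectra must share an identical grid")
  out <- specs[[1L]]
  out$y <- rowMeans(vapply(specs, `[[`, numeric(length(x)), "y"))
  out
}
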