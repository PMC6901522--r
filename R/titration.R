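#' Build per-residue pH titration curves
#'
#' Orders aligned peak lists by the pH recorded in their conditions and,
#' for each residue assigned in the lowest-pH (reference) spectrum,
#' computes the combined perturbation \eqn{\Delta\delta_{NH}} of every
#' other condition relative to that reference. The curve is zero at the
#' reference pH by construction. Residues missing from the reference are
#' excluded and reported via the `"excluded"` attribute; a residue's curve
#' only contains the pH values at which it is assigned.
#'
#' @param lists list of aligned `"peaklist"` objects, each with a pH in
#'   its condition.
#' @return named list (by assignment label) of `"titration_curve"` objects,
#'   each a list with `label`, `pH` (increasing), `delta_NH` (ppm, 0 at the
#'   reference) and `reference_pH`.
#' @export
build_titration_curves <- function(lists) {
  if (length(lists) < 2L) stop("need at least 2 pH conditions")
  pHs <- unname(vapply(lists, function(l) attr(l, "condition")$pH, 0.0))
  if (any(is.na(pHs))) stop("every peak list needs a pH in its condition")
  if (anyDuplicated(pHs)) stop("duplicate pH conditions")
  o <- order(pHs)
  lists <- lists[o]; pHs <- pHs[o]
  ref <- lists[[1L]]
  all_labels <- unique(unlist(lapply(lists, `[[`, "label")))
  excluded <- setdiff(all_labels, ref$label)
  curves <- lapply(ref$label, function(lab) {
    pH_pts <- pHs[1L]
    d_pts <- 0
    for (i in seq_along(lists)[-1L]) {
      j <- match(lab, lists[[i]]$label)
      if (is.na(j)) next
      k <- match(lab, ref$label)
      dH <- lists[[i]]$delta_H[j] - ref$delta_H[k]
      dN <- lists[[i]]$delta_N[j] - ref$delta_N[k]
      pH_pts <- c(pH_pts, pHs[i])
      d_pts <- c(d_pts, csp_combine(dH, dN))
    }
    structure(list(label = lab, pH = pH_pts, delta_NH = d_pts,
                   reference_pH = pHs[1L]),
              class = "titration_curve")
  })
  names(curves) <- ref$label
  attr(curves, "excluded") <- excluded
  curves
}

#' Construct a titration curve directly
#'
#' @param pH pH values (strictly increasing).
#' @param delta_NH combined perturbations in ppm relative to the first
#'   (reference) pH; must be 0 at the reference.
#' @param label assignment label.
#' @return a `"titration_curve"`.
#' @export
titration_curve <- function(pH, delta_NH, label = "") {
  stopifnot(length(pH) == length(delta_NH), length(pH) >= 2L)
  if (any(diff(pH) <= 0)) stop("pH values must be strictly increasing")
  structure(list(label = label, pH = as.numeric(pH),
                 delta_NH = as.numeric(delta_NH), reference_pH = pH[1L]),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve", if (nzchar(x$label)) x$label,
      sprintf(": %d points, pH %.2f-%.2f (reference pH %.2f)\n",
              length(x$pH), min(x$pH), max(x$pH), x$reference_pH))
  print(data.frame(pH = x$pH, delta_NH = x$delta_NH))
  invisible(x)
}

curve_is_flat <- function(curve, tol = 1e-12) {
  diff(range(curve$delta_NH)) <= tol
}

new_pka_fit <- function(method, pKa, coefficients, fitted, curve, rmse,
                        in_range, extra = list()) {
  structure(c(list(method = method, pKa = pKa,
                   coefficients = coefficients, fitted = fitted,
                   curve = curve, rmse = rmse, in_range = in_range),
              extra),
            class = "pka_fit")
}

#' Extract pKa by cubic inflection
#'
#' Fits an unweighted least-squares third-order polynomial
#' \eqn{y = a\,pH^3 + b\,pH^2 + c\,pH + d} to a
#' \eqn{\Delta\delta_{NH}}-vs-pH curve and reports the pKa as the
#' inflection point where the second derivative vanishes:
#' \eqn{pK_a = -b/(3a)}. The estimate is amplitude-independent (scaling
#' all perturbations by a positive constant leaves it unchanged). When the
#' inflection lies outside the sampled pH window, `in_range` is `FALSE`
#' and the value should be read as an estimate from an incomplete
#' titration only.
#'
#' @param curve a `"titration_curve"` with at least 4 points.
#' @return object of class `"pka_fit"` with `method = "cubic-inflection"`,
#'   `pKa`, polynomial `coefficients` (d, c, b, a), `rmse`, `in_range`.
#' @export
fit_cubic_pka <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (length(curve$pH) < 4L)
    stop("cubic fit needs at least 4 points, got ", length(curve$pH))
  if (curve_is_flat(curve)) stop("no titration: curve is flat")
  x <- curve$pH; y <- curve$delta_NH
  fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
  cf <- stats::coef(fit)                       # d, c, b, a
  a <- cf[[4L]]; b <- cf[[3L]]
  # scale-free smallness test for the leading coefficient
  a_scale <- max(abs(diff(range(y))), .Machine$double.eps) /
    max(diff(range(x)), 1)^3
  if (abs(a) < 1e-12 * a_scale || !is.finite(a))
    stop("no inflection: cubic term vanishes")
  pKa <- -b / (3 * a)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  new_pka_fit("cubic-inflection", pKa, cf, stats::fitted(fit), curve, rmse,
              in_range = pKa >= min(x) && pKa <= max(x))
}

#' Extract pKa by Henderson-Hasselbalch fitting
#'
#' Nonlinear least squares of the single-site titration model
#' \deqn{\delta(pH) = \delta_{acid} + \frac{\Delta}{1 + 10^{pK_a - pH}}}
#' to the perturbation curve; serves as an independent cross-check on the
#' cubic-inflection estimate.
#'
#' @param curve a `"titration_curve"` with at least 4 points.
#' @return a `"pka_fit"` with `method = "henderson-hasselbalch"`, `pKa`,
#'   `amplitude` (\eqn{\Delta}), `rmse`, `in_range`.
#' @export
fit_hh_pka <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (length(curve$pH) < 4L)
    stop("HH fit needs at least 4 points, got ", length(curve$pH))
  if (curve_is_flat(curve)) stop("no titration: curve is flat")
  x <- curve$pH; y <- curve$delta_NH
  amp0 <- max(y) - min(y)
  half <- min(y) + amp0 / 2
  pka0 <- stats::approx(y, x, xout = half, ties = mean)$y
  if (!is.finite(pka0)) pka0 <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d0 + amp / (1 + 10^(pka - x)),
      start = list(d0 = min(y), amp = amp0, pka = pka0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("HH fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  new_pka_fit("henderson-hasselbalch", unname(cf[["pka"]]), cf,
              stats::fitted(fit), curve, rmse,
              in_range = cf[["pka"]] >= min(x) && cf[["pka"]] <= max(x),
              extra = list(amplitude = unname(cf[["amp"]])))
}

#' @export
print.pka_fit <- function(x, digits = 1, ...) {
  est <- if (x$in_range) "" else " (estimate: inflection outside sampled window)"
  cat(sprintf("pKa fit [%s]%s: pKa = %.*f (rmse %.3g ppm)\n",
              x$method, est, digits, x$pKa, x$rmse))
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...) object$coefficients

#' @export
predict.pka_fit <- function(object, pH = object$curve$pH, ...) {
  cf <- object$coefficients
  if (object$method == "cubic-inflection")
    cf[[1L]] + cf[[2L]] * pH + cf[[3L]] * pH^2 + cf[[4L]] * pH^3
  else
    cf[["d0"]] + cf[["amp"]] / (1 + 10^(cf[["pka"]] - pH))
}

#' Normalize a titration curve to percent of maximum change
#'
#' Each perturbation is divided by the curve's maximum and multiplied by
#' 100, so the largest point reads 100%. Idempotent.
#'
#' @param curve a `"titration_curve"` with a positive maximum.
#' @return the curve with `delta_NH` in percent and attribute
#'   `"normalized"` set.
#' @export
percent_of_max <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  m <- max(curve$delta_NH)
  if (m <= 0) stop("cannot normalize a flat curve")
  curve$delta_NH <- 100 * curve$delta_NH / m
  attr(curve, "normalized") <- TRUE
  curve
}
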