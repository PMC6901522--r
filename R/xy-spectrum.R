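#' Construct a two-column XY spectrum
#'
#' Container for wavelength-scan data (CD in millidegrees, fluorescence in
#' counts). The x grid is sorted ascending (y permuted consistently) and
#' must be strictly monotone after sorting.
#'
#' @param x wavelength grid in nm.
#' @param y signal values.
#' @param x_unit,y_unit unit strings.
#' @param name condition/sample name.
#' @return object of class `"xy_spectrum"` with fields `x`, `y`, `meta`.
#' @export
xy_spectrum <- function(x, y, x_unit = "nm", y_unit = "", name = "") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("spectrum needs at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in spectrum")
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (any(diff(x) <= 0))
    stop("x grid contains duplicated values; must be strictly monotone")
  structure(list(x = x, y = y,
                 meta = list(x_unit = x_unit, y_unit = y_unit, name = name)),
            class = "xy_spectrum")
}

#' @export
print.xy_spectrum <- function(x, ...) {
  cat("XY spectrum", if (nzchar(x$meta$name)) paste0("'", x$meta$name, "'"),
      ":", length(x$x), "points,",
      sprintf("%g-%g %s", min(x$x), max(x$x), x$meta$x_unit))
  if (nzchar(x$meta$y_unit)) cat(",", x$meta$y_unit)
  cat("\n")
  invisible(x)
}

#' Read a two-column spectrum
#'
#' The delimiter is auto-detected among comma, tab and whitespace. Rows may
#' be in any x order; they are returned sorted ascending.
#'
#' @param file path or connection.
#' @inheritParams xy_spectrum
#' @return an `"xy_spectrum"`.
#' @export
read_xy_table <- function(file, x_unit = "nm", y_unit = "", name = "") {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("empty spectrum file")
  delim <- if (grepl(",", lines[1L])) "," else "\\s+|\t"
  fields <- strsplit(lines, delim)
  # drop a header row of non-numeric cells
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][1L]))))
    fields <- fields[-1L]
  if (length(fields) == 0L) stop("no data rows in spectrum file")
  xv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  yv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(!is.finite(xv) | !is.finite(yv))
  if (length(bad)) stop("row ", bad[1L], ": non-numeric value")
  xy_spectrum(xv, yv, x_unit = x_unit, y_unit = y_unit, name = name)
}

#' Write a spectrum as CSV
#'
#' Round-trips losslessly through [read_xy_table()].
#'
#' @param x an `"xy_spectrum"`.
#' @param file output path or connection.
#' @export
write_xy_table <- function(x, file) {
  stopifnot(inherits(x, "xy_spectrum"))
  writeLines(sprintf("%.17g,%.17g", x$x, x$y), file)
  invisible(x)
}
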