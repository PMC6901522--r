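#' Describe an experimental condition
#'
#' A condition attaches metadata (name, pH, ligand concentration) to a peak
#' list so downstream stages can order spectra along a titration axis.
#'
#' @param name free-text condition name.
#' @param pH optional pH in (0, 14).
#' @param ligand_conc optional ligand concentration (numeric).
#' @param ligand_unit unit string for `ligand_conc`, e.g. `"mM"`.
#' @return an object of class `"nmr_condition"`.
#' @export
condition <- function(name, pH = NA_real_, ligand_conc = NA_real_,
                      ligand_unit = "mM") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(pH) && (pH <= 0 || pH >= 14))
    stop("pH must lie in (0, 14), got ", pH)
  structure(list(name = name, pH = pH, ligand_conc = ligand_conc,
                 ligand_unit = ligand_unit),
            class = "nmr_condition")
}

#' @export
print.nmr_condition <- function(x, ...) {
  cat("condition:", x$name)
  if (!is.na(x$pH)) cat(", pH", x$pH)
  if (!is.na(x$ligand_conc)) cat(",", x$ligand_conc, x$ligand_unit, "ligand")
  cat("\n")
  invisible(x)
}

new_peaklist <- function(df, condition) {
  stopifnot(inherits(condition, "nmr_condition"))
  if (nrow(df) == 0L) stop("empty peak list")
  if (anyDuplicated(df$label))
    stop("duplicate assignment label: '",
         df$label[duplicated(df$label)][1L], "'")
  if (any(!is.finite(df$delta_N)) || any(!is.finite(df$delta_H)))
    stop("non-finite chemical shift value in peak list")
  rownames(df) <- NULL
  structure(df, condition = condition, class = c("peaklist", "data.frame"))
}

#' Construct a peak list from parsed components
#'
#' @param label character vector of assignment labels (e.g. `"H49N-H"`).
#' @param delta_N \eqn{^{15}N}{15N} chemical shifts in ppm (w1 dimension).
#' @param delta_H \eqn{^1H}{1H} chemical shifts in ppm (w2 dimension).
#' @param height optional signed peak intensities.
#' @param condition an [condition()] object.
#' @return object of class `"peaklist"` (a data frame with one row per
#'   assigned peak, at most one peak per label, and the condition attached
#'   as an attribute).
#' @export
peaklist <- function(label, delta_N, delta_H, height = NA_real_,
                     condition = protnmr::condition("unnamed")) {
  parsed <- parse_assignment_label(label)
  df <- cbind(parsed,
              data.frame(delta_N = as.numeric(delta_N),
                         delta_H = as.numeric(delta_H),
                         height = as.numeric(height)))
  new_peaklist(df, condition)
}

#' @export
print.peaklist <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("Peak list (", nrow(x), " peaks) - ", cond$name, sep = "")
  if (!is.na(cond$pH)) cat(", pH", cond$pH)
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more peaks\n")
  invisible(x)
}

#' Read a Sparky-format peak list
#'
#' Expects whitespace-delimited columns: assignment label, w1
#' (\eqn{^{15}N}{15N} ppm), w2 (\eqn{^1H}{1H} ppm) and an optional height.
#' A header line (e.g. `Assignment w1 w2`), blank lines and `#` comments are
#' tolerated. Column order can be swapped for exports that put the proton
#' dimension first.
#'
#' @param file path or connection.
#' @param condition an [condition()] object describing the spectrum.
#' @param swap_dims if `TRUE`, the first shift column is read as
#'   \eqn{^1H}{1H} and the second as \eqn{^{15}N}{15N}.
#' @return a `"peaklist"`.
#' @export
read_peaklist <- function(file, condition = protnmr::condition("unnamed"),
                          swap_dims = FALSE) {
  lines <- readLines(file)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- trimws(lines[keep])
  is_data <- function(ln) {
    f <- strsplit(ln, "\\s+")[[1L]]
    length(f) >= 3L && !is.na(suppressWarnings(as.numeric(f[2L])))
  }
  if (length(lines) && !is_data(lines[1L])) lines <- lines[-1L]  # header
  if (length(lines) == 0L) stop("empty peak list")
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", which(nf < 3L)[1L], ": expected at least 3 columns")
  w1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  w2 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(w1) | !is.finite(w2))
  if (length(bad))
    stop("line ", bad[1L], ": non-numeric chemical shift")
  height <- vapply(fields, function(f)
    if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else NA_real_,
    0.0)
  lab <- vapply(fields, `[`, "", 1L)
  if (swap_dims) { tmp <- w1; w1 <- w2; w2 <- tmp }
  peaklist(lab, delta_N = w1, delta_H = w2, height = height,
           condition = condition)
}

#' Write a peak list in Sparky format
#'
#' Emits a file that [read_peaklist()] reads back into an identical object
#' (shifts are written with full double precision).
#'
#' @param x a `"peaklist"`.
#' @param file output path or connection.
#' @export
write_peaklist <- function(x, file) {
  stopifnot(inherits(x, "peaklist"))
  has_h <- any(is.finite(x$height))
  hdr <- if (has_h) "Assignment w1 w2 Height" else "Assignment w1 w2"
  num <- function(v) sprintf("%.17g", v)
  body <- if (has_h)
    paste(x$label, num(x$delta_N), num(x$delta_H), num(x$height))
  else
    paste(x$label, num(x$delta_N), num(x$delta_H))
  writeLines(c(hdr, body), file)
  invisible(x)
}
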