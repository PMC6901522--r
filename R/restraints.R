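#' Read a distance-restraint table
#'
#' Supports the CYANA `.upl` layout (`res_i resname_i atom_i res_j
#' resname_j atom_j upper`) and a plain tabular layout (`res_i atom_i res_j
#' atom_j upper`). `#` comments and blank lines are skipped; every data
#' line is preserved as one record (no deduplication or ambiguity
#' expansion - classification conventions are applied downstream).
#'
#' @param file path or connection.
#' @param dialect `"cyana-upl"` (default) or `"tabular"`.
#' @return a data frame of class `"restraint_table"` with columns `res_i`,
#'   `resname_i`, `atom_i`, `res_j`, `resname_j`, `atom_j`, `upper`
#'   (upper-bound distance in Angstrom). Empty files yield zero rows.
#' @export
read_restraint_table <- function(file, dialect = c("cyana-upl", "tabular")) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  empty <- data.frame(res_i = integer(), resname_i = character(),
                      atom_i = character(), res_j = integer(),
                      resname_j = character(), atom_j = character(),
                      upper = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0L)
    return(structure(empty, class = c("restraint_table", "data.frame")))
  fields <- strsplit(lines, "\\s+")
  want <- if (dialect == "cyana-upl") 7L else 5L
  nf <- lengths(fields)
  if (any(nf < want))
    stop("line ", which(nf < want)[1L], ": expected ", want, " columns")
  g <- function(i) vapply(fields, `[`, "", i)
  df <- if (dialect == "cyana-upl") {
    data.frame(res_i = as.integer(g(1)), resname_i = g(2), atom_i = g(3),
               res_j = as.integer(g(4)), resname_j = g(5), atom_j = g(6),
               upper = as.numeric(g(7)), stringsAsFactors = FALSE)
  } else {
    data.frame(res_i = as.integer(g(1)), resname_i = NA_character_,
               atom_i = g(2), res_j = as.integer(g(3)),
               resname_j = NA_character_, atom_j = g(4),
               upper = as.numeric(g(5)), stringsAsFactors = FALSE)
  }
  if (any(!is.finite(df$upper)) || any(!is.finite(df$res_i)) ||
      any(!is.finite(df$res_j)))
    stop("non-numeric residue number or bound in restraint table")
  if (any(df$upper <= 0))
    stop("non-positive distance bound on line ", which(df$upper <= 0)[1L])
  if (any(df$res_i < 1L | df$res_j < 1L))
    stop("residue numbers must be >= 1")
  structure(df, class = c("restraint_table", "data.frame"))
}

#' Write a distance-restraint table in CYANA .upl layout
#'
#' @param x a `"restraint_table"` (or compatible data frame).
#' @param file output path or connection.
#' @export
write_restraint_table <- function(x, file) {
  rn_i <- ifelse(is.na(x$resname_i), "UNK", x$resname_i)
  rn_j <- ifelse(is.na(x$resname_j), "UNK", x$resname_j)
  writeLines(sprintf("%d %s %s %d %s %s %.17g",
                     x$res_i, rn_i, x$atom_i, x$res_j, rn_j, x$atom_j,
                     x$upper), file)
  invisible(x)
}

#' Classify distance restraints by residue separation
#'
#' NOE restraints are conventionally partitioned by the sequence separation
#' of the two residues: short-range (|i - j| <= 1), medium-range
#' (1 < |i - j| <= 5) and long-range (|i - j| > 5). Each record is counted
#' exactly once.
#'
#' @param restraints a `"restraint_table"` or data frame with `res_i`,
#'   `res_j`.
#' @return list of class `"restraint_classes"` with `short`, `medium`,
#'   `long` and `total` counts (`total = short + medium + long`).
#' @export
classify_restraints <- function(restraints) {
  sep <- abs(restraints$res_i - restraints$res_j)
  out <- list(short = sum(sep <= 1L),
              medium = sum(sep > 1L & sep <= 5L),
              long = sum(sep > 5L),
              total = length(sep))
  class(out) <- "restraint_classes"
  out
}

#' @export
print.restraint_classes <- function(x, ...) {
  cat("Distance restraints:", x$total, "total\n")
  cat(sprintf("  short-range  (|i-j| <= 1): %d\n", x$short))
  cat(sprintf("  medium-range (1 < |i-j| <= 5): %d\n", x$medium))
  cat(sprintf("  long-range   (|i-j| > 5): %d\n", x$long))
  invisible(x)
}
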