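#' Parse a Sparky-style assignment label
#'
#' Assignment labels name a residue and the pair of atoms giving rise to a
#' 2D cross-peak, e.g. `"H49N-H"` for the backbone amide of histidine 49
#' (the \eqn{^{15}N}{15N} nucleus correlated with its attached proton).
#'
#' @param text character vector of labels such as `"W77N-H"`.
#' @return A data frame with one row per label and columns `residue_type`
#'   (one-letter code), `residue_number` (integer), `atom1`, `atom2`, and
#'   `label` (the input text). Parsing then re-rendering with
#'   [format_assignment_label()] reproduces the input exactly.
#' @examples
#' parse_assignment_label("H49N-H")
#' @seealso [format_assignment_label()]
#' @export
parse_assignment_label <- function(text) {
  if (length(text) == 0L || any(!nzchar(text)))
    stop("assignment label must be a non-empty string")
  pat <- "^([A-Z])([0-9]+)([A-Za-z][A-Za-z0-9']*)-([A-Za-z][A-Za-z0-9']*)$"
  ok <- grepl(pat, text)
  if (any(!ok))
    stop("malformed assignment label: '", text[!ok][1L],
         "' (expected e.g. 'H49N-H')")
  m <- regmatches(text, regexec(pat, text))
  res <- data.frame(
    residue_type   = vapply(m, `[`, "", 2L),
    residue_number = as.integer(vapply(m, `[`, "", 3L)),
    atom1          = vapply(m, `[`, "", 4L),
    atom2          = vapply(m, `[`, "", 5L),
    label          = text,
    stringsAsFactors = FALSE
  )
  if (any(res$residue_number < 1L))
    stop("residue number must be >= 1 in label '",
         text[res$residue_number < 1L][1L], "'")
  res
}

#' Render an assignment label back to its text form
#'
#' @param x a data frame as returned by [parse_assignment_label()] (columns
#'   `residue_type`, `residue_number`, `atom1`, `atom2`).
#' @return character vector of labels.
#' @export
format_assignment_label <- function(x) {
  paste0(x$residue_type, x$residue_number, x$atom1, "-", x$atom2)
}
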