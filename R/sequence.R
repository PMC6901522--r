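# ExPASy-convention residue masses (Da); monoisotopic and average scales.
.residue_mass <- local({
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
          "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  avg <- c(57.0519, 71.0788, 87.0782, 97.1167, 99.1326, 101.1051,
           103.1388, 113.1594, 113.1594, 114.1038, 115.0886, 128.1307,
           128.1741, 129.1155, 131.1926, 137.1411, 147.1766, 156.1875,
           163.1760, 186.2132)
  mono <- c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841, 101.04768,
            103.00919, 113.08406, 113.08406, 114.04293, 115.02694,
            128.05858, 128.09496, 129.04259, 131.04049, 137.05891,
            147.06841, 156.10111, 163.06333, 186.07931)
  list(avg = stats::setNames(avg, aa), mono = stats::setNames(mono, aa))
})
.water_avg <- 18.01524
.water_mono <- 18.0105646863
.hydrogen_avg <- 1.00794
.hydrogen_mono <- 1.0078250319

#' Sequence-derived mass, extinction coefficient and concentration
#'
#' Computes average and monoisotopic molecular masses of a protein from
#' its one-letter sequence (sum of residue masses plus one water, minus
#' two hydrogen atoms per disulfide bond), and the 280-nm molar
#' extinction coefficient by the ProtParam rule
#' \eqn{\epsilon_{280} = 5500\,n_{Trp} + 1490\,n_{Tyr} +
#' 125\,n_{cystine}} (in M\eqn{^{-1}}cm\eqn{^{-1}}).
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param n_disulfides number of disulfide bonds (each removes 2 H and
#'   contributes one cystine to \eqn{\epsilon_{280}}).
#' @return object of class `"sequence_props"`: `average_mass`,
#'   `monoisotopic_mass` (Da), `extinction_280`, residue counts,
#'   `n_residues`, `n_disulfides`.
#' @examples
#' sequence_props("G")   # 75.07 Da (glycine)
#' @export
sequence_props <- function(sequence, n_disulfides = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- which(!(res %in% names(.residue_mass$avg)))
  if (length(unknown))
    stop("unknown residue '", res[unknown[1L]], "' at position ",
         unknown[1L])
  n_cys <- sum(res == "C")
  if (2L * n_disulfides > n_cys)
    stop("n_disulfides = ", n_disulfides, " requires ", 2L * n_disulfides,
         " cysteines but sequence has ", n_cys)
  avg <- sum(.residue_mass$avg[res]) + .water_avg -
    2 * .hydrogen_avg * n_disulfides
  mono <- sum(.residue_mass$mono[res]) + .water_mono -
    2 * .hydrogen_mono * n_disulfides
  eps <- 5500 * sum(res == "W") + 1490 * sum(res == "Y") +
    125 * n_disulfides
  structure(list(average_mass = avg, monoisotopic_mass = mono,
                 extinction_280 = eps,
                 n_residues = length(res),
                 n_trp = sum(res == "W"), n_tyr = sum(res == "Y"),
                 n_cys = n_cys, n_disulfides = as.integer(n_disulfides)),
            class = "sequence_props")
}

#' @export
print.sequence_props <- function(x, ...) {
  cat(sprintf("Sequence: %d residues, %d disulfide(s)\n",
              x$n_residues, x$n_disulfides))
  cat(sprintf("  average mass:      %.2f Da (%.2f kDa)\n",
              x$average_mass, x$average_mass / 1000))
  cat(sprintf("  monoisotopic mass: %.2f Da\n", x$monoisotopic_mass))
  cat(sprintf("  epsilon(280 nm):   %d /M/cm\n", x$extinction_280))
  invisible(x)
}

#' Protein concentration by Beer's law
#'
#' \eqn{c = A_{280} / (\epsilon \cdot l)}.
#'
#' @param A280 absorbance at 280 nm.
#' @param epsilon molar extinction coefficient in /M/cm (or a
#'   `"sequence_props"` object).
#' @param path_cm cuvette pathlength in cm.
#' @return molar concentration.
#' @export
beer_concentration <- function(A280, epsilon, path_cm = 1) {
  if (inherits(epsilon, "sequence_props")) epsilon <- epsilon$extinction_280
  stopifnot(epsilon > 0, path_cm > 0)
  A280 / (epsilon * path_cm)
}
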