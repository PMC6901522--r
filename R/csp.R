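#' Combined amide chemical shift perturbation
#'
#' The combined \eqn{^1H,^{15}N}{1H,15N} perturbation scales the nitrogen
#' displacement by 1/5 to put both dimensions on a comparable ppm scale:
#' \deqn{\Delta\delta_{NH} = \sqrt{(\Delta\delta_H)^2 +
#'   (\Delta\delta_N/5)^2}}
#'
#' @param delta_H proton displacement(s) in ppm.
#' @param delta_N nitrogen displacement(s) in ppm.
#' @return non-negative combined perturbation(s) in ppm. Depends only on
#'   the magnitudes of the displacements.
#' @examples
#' csp_combine(0.03, 0.20)  # 0.05
#' @export
csp_combine <- function(delta_H, delta_N) {
  sqrt(delta_H^2 + (delta_N / 5)^2)
}

#' Per-residue chemical shift perturbations between two conditions
#'
#' For every assignment label present in both peak lists, computes the
#' displacements \eqn{\Delta\delta_H}, \eqn{\Delta\delta_N} (condition `b`
#' minus condition `a`) and the combined perturbation [csp_combine()].
#'
#' @param a,b `"peaklist"` objects sharing assignment labels.
#' @return data frame of class `"csp_table"`: `label`, `residue_type`,
#'   `residue_number`, `delta_H`, `delta_N`, `delta_NH`, ordered by residue
#'   number. The attribute `conditions` records the pair used.
#' @export
compute_csp <- function(a, b) {
  stopifnot(inherits(a, "peaklist"), inherits(b, "peaklist"))
  common <- intersect(a$label, b$label)
  if (length(common) == 0L)
    stop("no common assignment labels between the two peak lists")
  ia <- match(common, a$label); ib <- match(common, b$label)
  dH <- b$delta_H[ib] - a$delta_H[ia]
  dN <- b$delta_N[ib] - a$delta_N[ia]
  out <- data.frame(label = common,
                    residue_type = a$residue_type[ia],
                    residue_number = a$residue_number[ia],
                    delta_H = dH, delta_N = dN,
                    delta_NH = csp_combine(dH, dN),
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_number), ]
  rownames(out) <- NULL
  structure(out,
            conditions = c(attr(a, "condition")$name,
                           attr(b, "condition")$name),
            class = c("csp_table", "data.frame"))
}

#' Align peak lists to a reference peak
#'
#' Spectra recorded under different conditions can carry small global
#' referencing offsets. A constant (\eqn{\Delta\delta_H},
#' \eqn{\Delta\delta_N}) offset is subtracted from every peak of each list
#' so that the chosen reference peak (a pH-insensitive amide, e.g. the
#' W77 backbone amide) coincides with its position in the first list. The
#' reference peak's perturbation across aligned lists is exactly zero.
#'
#' @param lists a (preferably named) list of `"peaklist"` objects; the
#'   first is the positional anchor.
#' @param reference assignment label of the reference peak, e.g.
#'   `"W77N-H"`.
#' @return list of aligned `"peaklist"` objects in the input order, with
#'   per-list offsets attached as attribute `"offsets"`.
#' @export
align_to_reference <- function(lists, reference) {
  stopifnot(is.list(lists), length(lists) >= 1L)
  for (i in seq_along(lists)) {
    if (!reference %in% lists[[i]]$label) {
      nm <- attr(lists[[i]], "condition")$name
      stop("reference peak '", reference, "' missing from condition '",
           nm, "'")
    }
  }
  ref1 <- lists[[1L]][match(reference, lists[[1L]]$label), ]
  offsets <- matrix(0, nrow = length(lists), ncol = 2L,
                    dimnames = list(names(lists), c("delta_H", "delta_N")))
  out <- lists
  for (i in seq_along(lists)) {
    ri <- lists[[i]][match(reference, lists[[i]]$label), ]
    off_H <- ri$delta_H - ref1$delta_H
    off_N <- ri$delta_N - ref1$delta_N
    offsets[i, ] <- c(off_H, off_N)
    out[[i]]$delta_H <- lists[[i]]$delta_H - off_H
    out[[i]]$delta_N <- lists[[i]]$delta_N - off_N
  }
  attr(out, "offsets") <- offsets
  out
}

#' Tukey-fence binning of chemical shift perturbations
#'
#' Bins combined perturbations into `n_bins` color classes. The upper
#' bound `b` of the first bin is the Tukey outlier fence
#' \eqn{Q_3 + 1.5 \times IQR} of a reference perturbation distribution -
#' typically the \eqn{\Delta\delta_{NH}} values between two replicate
#' spectra of nominally identical condition, so that bin 1 holds
#' perturbations indistinguishable from replicate noise. Consecutive bin
#' boundaries are multiples of `b`; bin `k` covers `((k-1)b, kb]` and the
#' last bin is unbounded above. A value of exactly 0 falls in bin 1.
#'
#' @param values a `"csp_table"` (or numeric vector of perturbations).
#' @param reference_values reference distribution: a `"csp_table"` or
#'   numeric vector. Ignored when `first_bound` is given.
#' @param n_bins number of bins (default 10).
#' @param first_bound optional explicit first-bin upper bound in ppm,
#'   overriding the fence.
#' @param quartile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation on the sorted sample).
#' @return list of class `"csp_binning"` with `scheme` (list: `n_bins`,
#'   `first_bound`, `bounds`, `quartile_type`) and `map` (data frame:
#'   `label`, `residue_number`, `delta_NH`, `bin`).
#' @export
bin_csp <- function(values, reference_values = NULL, n_bins = 10L,
                    first_bound = NULL, quartile_type = 7L) {
  v <- if (inherits(values, "csp_table")) values$delta_NH else as.numeric(values)
  if (any(v < 0)) stop("combined perturbations cannot be negative")
  if (is.null(first_bound)) {
    if (is.null(reference_values))
      stop("supply reference_values (replicate-pair perturbations) or first_bound")
    r <- if (inherits(reference_values, "csp_table"))
      reference_values$delta_NH else as.numeric(reference_values)
    if (length(r) == 0L) stop("reference distribution is empty")
    q <- stats::quantile(r, c(0.25, 0.75), type = quartile_type,
                         names = FALSE)
    first_bound <- q[2L] + 1.5 * (q[2L] - q[1L])
  }
  if (first_bound <= 0)
    stop("first bin bound is not positive (reference values all zero?); ",
         "supply an explicit first_bound")
  bin <- pmin(pmax(ceiling(v / first_bound), 1L), n_bins)
  map <- if (inherits(values, "csp_table"))
    data.frame(label = values$label, residue_number = values$residue_number,
               delta_NH = v, bin = bin, stringsAsFactors = FALSE)
  else data.frame(label = NA_character_, residue_number = NA_integer_,
                  delta_NH = v, bin = bin)
  scheme <- list(n_bins = as.integer(n_bins), first_bound = first_bound,
                 bounds = c(first_bound * seq_len(n_bins - 1L), Inf),
                 quartile_type = quartile_type)
  structure(list(scheme = scheme, map = map), class = "csp_binning")
}

#' @export
print.csp_binning <- function(x, ...) {
  cat(sprintf("CSP binning: %d bins, first bound %.4g ppm (Tukey fence)\n",
              x$scheme$n_bins, x$scheme$first_bound))
  print(table(bin = factor(x$map$bin, levels = seq_len(x$scheme$n_bins))))
  invisible(x)
}

#' Map perturbation bins onto a structure
#'
#' Writes a copy of the ensemble's first model with each residue's bin
#' index in the B-factor column (missing residues get the sentinel -1) and
#' a plain-text per-residue color table on a gray-to-green ramp (missing =
#' black), ready for molecular-graphics coloring.
#'
#' @param binning a `"csp_binning"` from [bin_csp()].
#' @param ensemble a `"structure_ensemble"` with numbering consistent with
#'   the peak lists.
#' @param pdb_file,color_file output paths (either may be `NULL` to skip).
#' @return invisibly, a data frame with `resno`, `bin`, `color` for every
#'   residue of the structure.
#' @export
map_bins_to_structure <- function(binning, ensemble, pdb_file = NULL,
                                  color_file = NULL) {
  stopifnot(inherits(binning, "csp_binning"))
  validate_ensemble(ensemble)
  resnos <- unique(ensemble$atoms$resno)
  if (!any(binning$map$residue_number %in% resnos))
    stop("no residue overlap between bin map and structure")
  bin_of <- binning$map$bin[match(resnos, binning$map$residue_number)]
  n <- binning$scheme$n_bins
  # gray (bin 1) -> green (bin n); black for unassigned residues
  ramp <- grDevices::colorRampPalette(c("gray70", "darkgreen"))(n)
  col <- ifelse(is.na(bin_of), "black", ramp[pmin(bin_of, n)])
  tab <- data.frame(resno = resnos,
                    bin = ifelse(is.na(bin_of), -1L, bin_of),
                    color = col, stringsAsFactors = FALSE)
  if (!is.null(pdb_file)) {
    b <- tab$bin[match(ensemble$atoms$resno, tab$resno)]
    bio3d::write.pdb(file = pdb_file,
                     xyz = ensemble$xyz[1L, ],
                     resno = ensemble$atoms$resno,
                     resid = ensemble$atoms$resid,
                     elety = ensemble$atoms$elety,
                     chain = ifelse(is.na(ensemble$atoms$chain), "A",
                                    ensemble$atoms$chain),
                     b = as.numeric(b))
  }
  if (!is.null(color_file))
    utils::write.table(tab, color_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}

#' Compare two conditions for spectral perturbation
#'
#' Reports the per-residue perturbation table between two aligned peak
#' lists and a verdict: `"unperturbed"` iff the maximum combined
#' perturbation is below `threshold`, otherwise `"perturbed"` with the
#' residues exceeding it (the criterion used to conclude that, e.g., a
#' fourfold molar excess of calcium leaves a spectrum unperturbed).
#'
#' @param a,b aligned `"peaklist"` objects.
#' @param threshold perturbation threshold in ppm (default 0.02).
#' @return list of class `"csp_comparison"`: `csp` (the `"csp_table"`),
#'   `threshold`, `verdict`, `exceeding` (labels above threshold).
#' @export
compare_conditions <- function(a, b, threshold = 0.02) {
  tab <- compute_csp(a, b)
  exceeding <- tab$label[tab$delta_NH >= threshold]
  structure(list(csp = tab, threshold = threshold,
                 verdict = if (length(exceeding)) "perturbed" else "unperturbed",
                 exceeding = exceeding),
            class = "csp_comparison")
}

#' @export
print.csp_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison: %s (max %.4g ppm vs threshold %.4g ppm)\n",
              x$verdict, max(x$csp$delta_NH), x$threshold))
  if (length(x$exceeding))
    cat("  residues exceeding threshold:",
        paste(x$exceeding, collapse = ", "), "\n")
  invisible(x)
}
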