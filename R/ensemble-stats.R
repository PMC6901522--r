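#' Define an ordered-region residue selection
#'
#' Residue ranges (inclusive) over which ensemble statistics are computed,
#' e.g. the ordered residues 35-126 and 133-168 of a structure whose
#' termini and a long loop are disordered. Ranges must be ascending and
#' non-overlapping.
#'
#' @param ranges list of length-2 integer vectors `c(first, last)`.
#' @param atom_selection `"backbone"` (N, CA, C; optionally O) or
#'   `"heavy"` (all non-hydrogen atoms).
#' @param include_O include the carbonyl O in the backbone selection.
#' @return object of class `"region_set"`.
#' @export
region_set <- function(ranges = list(c(35L, 126L), c(133L, 168L)),
                       atom_selection = c("backbone", "heavy"),
                       include_O = FALSE) {
  atom_selection <- match.arg(atom_selection)
  stopifnot(is.list(ranges), length(ranges) >= 1L)
  m <- do.call(rbind, lapply(ranges, function(r) {
    stopifnot(length(r) == 2L, r[1L] <= r[2L])
    as.integer(r)
  }))
  if (nrow(m) > 1L) {
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L]))
      stop("residue ranges must be non-overlapping and ascending")
  }
  structure(list(ranges = m, atom_selection = atom_selection,
                 include_O = include_O),
            class = "region_set")
}

#' Residue numbers covered by a region set
#'
#' @param region a `"region_set"`.
#' @return sorted integer vector of residue numbers.
#' @export
region_residues <- function(region) {
  stopifnot(inherits(region, "region_set"))
  sort(unique(unlist(apply(region$ranges, 1L,
                           function(r) seq.int(r[1L], r[2L]),
                           simplify = FALSE))))
}

#' Read residue ranges from a text file
#'
#' One range per line, `first last` (whitespace-separated); `#` comments
#' allowed.
#'
#' @param file path.
#' @inheritParams region_set
#' @return a `"region_set"`.
#' @export
read_region_set <- function(file, atom_selection = c("backbone", "heavy"),
                            include_O = FALSE) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  ranges <- lapply(strsplit(lines, "\\s+"),
                   function(f) as.integer(f[1:2]))
  region_set(ranges, atom_selection = match.arg(atom_selection),
             include_O = include_O)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired point sets, via SVD of the cross-covariance of the centered
#' coordinates; reflections are excluded by sign-correcting the smallest
#' singular direction.
#'
#' @param mobile,target numeric n x 3 matrices of paired coordinates
#'   (n >= 3, non-degenerate).
#' @return list of class `"superposition"`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `coords` (mobile after
#'   the fitted motion). The motion maps `mobile` onto `target` as
#'   `coords = mobile %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm); B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  if (qr(A)$rank < 2L)
    stop("degenerate geometry: points are (nearly) collinear")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps centered A rows
  R <- t(R)                                    # row-vector convention
  coords <- sweep(A %*% R, 2L, ct, `+`)
  rmsd <- sqrt(mean(rowSums((coords - target)^2)))
  list(rotation = R, translation = as.vector(ct - cm %*% R), rmsd = rmsd,
       coords = coords)
}

select_region_atoms <- function(ensemble, region) {
  at <- ensemble$atoms
  in_res <- at$resno %in% region_residues(region)
  sel <- if (region$atom_selection == "backbone") {
    bb <- c("N", "CA", "C", if (region$include_O) "O")
    in_res & trimws(at$elety) %in% bb
  } else {
    in_res & !is_hydrogen(at$elety)
  }
  which(sel)
}

#' Average pairwise ensemble RMSD against the first model
#'
#' Superposes each model 2..N onto model 1 (taken as the lowest-energy
#' conformer) over the selected atoms of the ordered region and reports
#' the RMSD over those atoms, summarized as mean and standard deviation
#' over models.
#'
#' @param ensemble a `"structure_ensemble"` with >= 2 models.
#' @param region a `"region_set"` (atom selection and residue ranges).
#' @return list of class `"ensemble_rmsd"`: `mean`, `sd`, `per_model`
#'   (RMSD of each model 2..N), `n_atoms` used.
#' @export
ensemble_rmsd <- function(ensemble, region = region_set()) {
  validate_ensemble(ensemble)
  if (ensemble$n_models < 2L) stop("ensemble has fewer than 2 models")
  idx <- select_region_atoms(ensemble, region)
  if (length(idx) == 0L) stop("region selects no atoms")
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  tgt <- matrix(ensemble$xyz[1L, cols], ncol = 3L, byrow = TRUE)
  per <- vapply(2:ensemble$n_models, function(k) {
    mob <- matrix(ensemble$xyz[k, cols], ncol = 3L, byrow = TRUE)
    kabsch_superpose(mob, tgt)$rmsd
  }, 0.0)
  structure(list(mean = mean(per), sd = stats::sd(per), per_model = per,
                 n_atoms = length(idx),
                 atom_selection = region$atom_selection),
            class = "ensemble_rmsd")
}

#' @export
print.ensemble_rmsd <- function(x, ...) {
  cat(sprintf(
    "Ensemble RMSD vs model 1 (%s, %d atoms): %.2f +/- %.2f Angstrom over %d models\n",
    x$atom_selection, x$n_atoms, x$mean, x$sd, length(x$per_model) + 1L))
  invisible(x)
}

#' Interface residues between two structures at a distance cutoff
#'
#' Residues of structure `a` having at least one heavy atom within
#' `cutoff` of any heavy atom of structure `b` (hydrogens excluded on
#' both sides). Monotone in the cutoff.
#'
#' @param a,b data frames with columns `resno`, `elety`, `x`, `y`, `z`
#'   (e.g. from [ensemble_model()]).
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return sorted integer vector of residue numbers of `a`.
#' @export
interface_residues <- function(a, b, cutoff = 5.0) {
  stopifnot(nrow(a) > 0L, nrow(b) > 0L, cutoff > 0)
  a <- a[!is_hydrogen(a$elety), , drop = FALSE]
  b <- b[!is_hydrogen(b$elety), , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) return(integer())
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  # squared pairwise distances: |u|^2 + |v|^2 - 2 u.v
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  near <- apply(d2 <= cutoff^2 + 1e-12, 1L, any)
  sort(unique(a$resno[near]))
}
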