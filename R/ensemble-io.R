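#' Read a multi-model PDB file as a structure ensemble
#'
#' Parses a standard PDB file (MODEL/ENDMDL records, or a single implicit
#' model) via \pkg{bio3d}. Models are kept in file order; by deposition
#' convention model 1 is treated downstream as the lowest-energy conformer.
#' All models must share the same atoms in the same order; alternate
#' locations other than blank or `'A'` are rejected.
#'
#' @param file path to a PDB file.
#' @return object of class `"structure_ensemble"`: a list with `atoms`
#'   (data frame: `elety`, `resid`, `chain`, `resno` for the shared atom
#'   composition), `xyz` (matrix, one row per model, columns x1,y1,z1,...),
#'   `n_models` and `n_atoms`.
#' @export
read_ensemble <- function(file) {
  lines <- readLines(file)
  atom_ln <- grepl("^ATOM  |^HETATM", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(atom_ln[s:e]), model_starts, ends)
    if (length(unique(counts)) != 1L)
      stop("models differ in atom count: model 1 has ", counts[1L],
           " atoms, model ", which(counts != counts[1L])[1L], " has ",
           counts[counts != counts[1L]][1L])
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  alt <- pdb$atom$alt
  if (!is.null(alt) && any(!(is.na(alt) | alt %in% c("", "A"))))
    stop("alternate location indicators other than blank/'A' not supported")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  ens <- structure(
    list(atoms = pdb$atom[, c("elety", "resid", "chain", "resno")],
         xyz = unclass(xyz),
         n_models = nrow(xyz),
         n_atoms = nrow(pdb$atom)),
    class = "structure_ensemble")
  validate_ensemble(ens)
}

validate_ensemble <- function(ens) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (ens$n_models < 1L) stop("ensemble must contain at least one model")
  if (ncol(ens$xyz) != 3L * ens$n_atoms)
    stop("coordinate matrix does not match atom table")
  if (any(!is.finite(ens$xyz))) stop("non-finite coordinates in ensemble")
  key <- with(ens$atoms, paste(chain, resno, elety))
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) record: ",
         key[duplicated(key)][1L])
  ens
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("Structure ensemble:", x$n_models, "model(s),", x$n_atoms,
      "atoms per model\n")
  cat("  residues", min(x$atoms$resno), "-", max(x$atoms$resno), "\n")
  invisible(x)
}

#' Extract one model's coordinates
#'
#' @param ensemble a `"structure_ensemble"`.
#' @param model model index (1 = lowest-energy conformer by convention).
#' @return data frame with `elety`, `resid`, `chain`, `resno`, `x`, `y`, `z`.
#' @export
ensemble_model <- function(ensemble, model = 1L) {
  validate_ensemble(ensemble)
  stopifnot(model >= 1L, model <= ensemble$n_models)
  v <- ensemble$xyz[model, ]
  cbind(ensemble$atoms,
        data.frame(x = v[c(TRUE, FALSE, FALSE)],
                   y = v[c(FALSE, TRUE, FALSE)],
                   z = v[c(FALSE, FALSE, TRUE)]))
}

# PDB atom names starting with H (optionally digit-prefixed) are hydrogens
is_hydrogen <- function(elety) grepl("^[0-9]*H", trimws(elety))
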