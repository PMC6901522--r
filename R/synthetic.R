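# Run expr with a local, seeded RNG stream; the caller's RNG state is
# untouched, so identical (scenario, seed) pairs give identical output.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a pH-titration simulation scenario
#'
#' Describes a set of residues whose amide shifts follow single-site
#' Henderson-Hasselbalch titration
#' \eqn{\delta(pH) = \delta_{acid} + \Delta/(1 + 10^{pK_a - pH})},
#' applied independently to the H and N dimensions, plus pH-insensitive
#' residues (`pKa = NA`). Default amplitudes are capped at 0.12 ppm (H)
#' and 0.6 ppm (N), resembling histidine-neighborhood excursions in amide
#' titrations of small proteins; the default noise of 0.005 ppm is on the
#' order of digital resolution.
#'
#' @param residues data frame with columns `label`, `pKa` (NA for flat),
#'   `amp_H`, `amp_N` (titration amplitudes, ppm), `base_H`, `base_N`
#'   (acid-limit shifts, ppm). If `NULL`, a default 30-residue mixture of
#'   titrating and flat residues is generated.
#' @param pH_grid pH sampling points; default
#'   `c(5.5, 6.0, 6.25, 6.5, 7.0, 7.4, 8.0)`.
#' @param noise_sd additive Gaussian noise per dimension per condition
#'   (ppm).
#' @param seed integer seed.
#' @return object of class `"titration_scenario"`.
#' @export
titration_scenario <- function(residues = NULL,
                               pH_grid = c(5.5, 6.0, 6.25, 6.5, 7.0, 7.4, 8.0),
                               noise_sd = 0.005, seed = 1L) {
  if (is.null(residues)) {
    residues <- with_seed(seed + 1000L, {
      n <- 30L
      titr <- rep(c(TRUE, FALSE), length.out = n)
      data.frame(
        label = sprintf("%s%dN-H",
                        sample(c("A", "G", "L", "V", "H", "E", "K", "S"),
                               n, replace = TRUE),
                        seq(30L, 29L + n)),
        pKa = ifelse(titr, stats::runif(n, 5.8, 7.0), NA_real_),
        amp_H = ifelse(titr, stats::runif(n, 0.04, 0.12), 0),
        amp_N = ifelse(titr, stats::runif(n, 0.2, 0.6), 0),
        base_H = stats::runif(n, 7.5, 9.5),
        base_N = stats::runif(n, 105, 130),
        stringsAsFactors = FALSE)
    })
  }
  stopifnot(all(c("label", "pKa", "amp_H", "amp_N", "base_H", "base_N")
                %in% names(residues)))
  if (any(diff(sort(pH_grid)) <= 0)) stop("pH grid must not repeat values")
  structure(list(residues = residues, pH_grid = sort(pH_grid),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "titration_scenario")
}

#' Simulate peak lists across a pH titration
#'
#' One peak list per pH in the scenario grid; flat residues sit at their
#' base shifts at every pH (up to noise) and titrating residues follow
#' the Henderson-Hasselbalch curve in both dimensions. A ground-truth
#' table travels with the data for closed-loop recovery tests.
#'
#' @param scenario a [titration_scenario()].
#' @return list with `peaklists` (named by pH, each a `"peaklist"` whose
#'   condition carries the pH) and `truth` (the scenario residue table).
#' @export
make_titration_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "titration_scenario"))
  r <- scenario$residues
  hh <- function(base, amp, pKa, pH)
    ifelse(is.na(pKa), base, base + amp / (1 + 10^(pKa - pH)))
  with_seed(scenario$seed, {
    pls <- lapply(scenario$pH_grid, function(p) {
      dH <- hh(r$base_H, r$amp_H, r$pKa, p) +
        stats::rnorm(nrow(r), 0, scenario$noise_sd)
      dN <- hh(r$base_N, r$amp_N, r$pKa, p) +
        stats::rnorm(nrow(r), 0, scenario$noise_sd)
      peaklist(r$label, delta_N = dN, delta_H = dH,
               condition = condition(sprintf("pH %.2f", p), pH = p))
    })
    names(pls) <- sprintf("%.2f", scenario$pH_grid)
    list(peaklists = pls, truth = r)
  })
}

#' Simulate exponential relaxation decays
#'
#' \eqn{I(t) = I_0 e^{-t/T} (1 + \epsilon)}, \eqn{\epsilon \sim N(0,
#' sd)} (multiplicative noise), one series per residue on the requested
#' delay grid.
#'
#' @param T_true vector of true time constants in ms (one per residue).
#' @param delays delay grid in ms; default the 11-point 10-210 ms T2
#'   schedule. Use `seq(80, 2000, length.out = 11)`-style grids for T1.
#' @param noise_sd multiplicative noise standard deviation.
#' @param I0 common initial intensity.
#' @param experiment `"T2"` or `"T1"` (label only).
#' @param seed integer seed.
#' @return list with `series` (list of `"decay_series"`) and `truth`
#'   (data frame `label`, `T_true`).
#' @export
make_decay_dataset <- function(T_true,
                               delays = c(10, 30, 50, 70, 90, 110, 130,
                                          150, 170, 190, 210),
                               noise_sd = 0, I0 = 100,
                               experiment = c("T2", "T1"), seed = 1L) {
  experiment <- match.arg(experiment)
  with_seed(seed, {
    labs <- sprintf("A%dN-H", seq_along(T_true) + 30L)
    series <- lapply(seq_along(T_true), function(i) {
      I <- I0 * exp(-delays / T_true[i]) *
        (1 + stats::rnorm(length(delays), 0, noise_sd))
      decay_series(delays, I, label = labs[i], experiment = experiment)
    })
    list(series = series,
         truth = data.frame(label = labs, T_true = T_true,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a Gaussian-jittered coordinate ensemble
#'
#' Model 1 is the unperturbed base structure; models 2..N add i.i.d.
#' Gaussian jitter with standard deviation `jitter_sd` to every
#' coordinate, so the expected pre-superposition RMSD of each jittered
#' model is \eqn{\sigma\sqrt{3}}.
#'
#' @param n_models number of models (>= 1).
#' @param jitter_sd per-coordinate jitter in Angstrom.
#' @param base optional n x 3 coordinate matrix; by default a compact
#'   random 125-residue poly-alanine-like backbone cloud is generated.
#' @param n_atoms number of atoms when generating a base (default 500).
#' @param seed integer seed.
#' @return a `"structure_ensemble"` with attribute `"truth"` (list:
#'   `jitter_sd`, `expected_rmsd`).
#' @export
make_ensemble <- function(n_models = 20L, jitter_sd = 0.5, base = NULL,
                          n_atoms = 500L, seed = 1L) {
  stopifnot(n_models >= 1L, jitter_sd >= 0)
  with_seed(seed, {
    if (is.null(base)) {
      # self-avoiding-ish random walk to mimic a compact chain
      steps <- matrix(stats::rnorm(3L * n_atoms), ncol = 3L)
      steps <- steps / sqrt(rowSums(steps^2)) * 1.5
      base <- apply(steps, 2L, cumsum)
      base <- base - matrix(colMeans(base), n_atoms, 3L, byrow = TRUE)
    }
    base <- as.matrix(base)
    n_atoms <- nrow(base)
    bb <- c("N", "CA", "C", "O")
    atoms <- data.frame(
      elety = bb[(seq_len(n_atoms) - 1L) %% 4L + 1L],
      resid = "ALA", chain = "A",
      resno = (seq_len(n_atoms) - 1L) %/% 4L + 1L,
      stringsAsFactors = FALSE)
    xyz <- matrix(0, n_models, 3L * n_atoms)
    xyz[1L, ] <- as.vector(t(base))
    if (n_models > 1L)
      for (k in 2:n_models)
        xyz[k, ] <- as.vector(t(base)) +
          stats::rnorm(3L * n_atoms, 0, jitter_sd)
    ens <- structure(list(atoms = atoms, xyz = xyz, n_models = n_models,
                          n_atoms = n_atoms),
                     class = "structure_ensemble")
    attr(ens, "truth") <- list(jitter_sd = jitter_sd,
                               expected_rmsd = jitter_sd * sqrt(3))
    validate_ensemble(ens)
  })
}

#' Generate a restraint set with prescribed range-class counts
#'
#' Draws residue pairs so that the sequence separation |i - j| lands in
#' the requested class, guaranteeing [classify_restraints()] returns
#' exactly the requested (short, medium, long) counts.
#'
#' @param n_short,n_medium,n_long counts per class.
#' @param n_residues chain length (must allow the requested separations).
#' @param seed integer seed.
#' @return a `"restraint_table"`.
#' @export
make_restraint_set <- function(n_short, n_medium, n_long,
                               n_residues = 150L, seed = 1L) {
  if (n_long > 0 && n_residues < 7L)
    stop("long-range restraints need |i-j| > 5: chain too short")
  if (n_medium > 0 && n_residues < 3L)
    stop("medium-range restraints need |i-j| in 2..5: chain too short")
  atoms <- c("HA", "HB", "HN", "HG", "HD")
  with_seed(seed, {
    resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
    draw <- function(n, sep_min, sep_max) {
      if (n == 0L) return(NULL)
      sep <- resample(seq.int(sep_min, min(sep_max, n_residues - 1L)), n)
      i <- vapply(sep, function(s) sample.int(n_residues - s, 1L), 0L)
      data.frame(res_i = i, resname_i = "ALA",
                 atom_i = sample(atoms, n, replace = TRUE),
                 res_j = i + sep, resname_j = "ALA",
                 atom_j = sample(atoms, n, replace = TRUE),
                 upper = round(stats::runif(n, 2.5, 6.0), 2),
                 stringsAsFactors = FALSE)
    }
    df <- rbind(draw(n_short, 0L, 1L), draw(n_medium, 2L, 5L),
                draw(n_long, 6L, n_residues - 1L))
    structure(df, class = c("restraint_table", "data.frame"))
  })
}

#' Simulate a unimodal emission spectrum
#'
#' Gaussian-shaped peak plus additive noise on the requested wavelength
#' grid (default the 305-400 nm, 0.5 nm fluorescence grid).
#'
#' @param center peak center in nm (must lie inside the grid).
#' @param width Gaussian sigma in nm.
#' @param noise_sd additive noise as a fraction of the peak amplitude.
#' @param grid wavelength grid in nm.
#' @param amplitude peak amplitude (counts).
#' @param seed integer seed.
#' @return an `"xy_spectrum"` with attribute `"truth"` (list `center`,
#'   `width`).
#' @export
make_emission_spectrum <- function(center = 338, width = 25,
                                   noise_sd = 0,
                                   grid = seq(305, 400, by = 0.5),
                                   amplitude = 1e5, seed = 1L) {
  if (center < min(grid) || center > max(grid))
    stop("peak center lies outside the wavelength grid")
  with_seed(seed, {
    y <- amplitude * exp(-(grid - center)^2 / (2 * width^2)) +
      stats::rnorm(length(grid), 0, noise_sd * amplitude)
    s <- xy_spectrum(grid, y, y_unit = "counts",
                     name = sprintf("emission %.1f nm", center))
    attr(s, "truth") <- list(center = center, width = width)
    s
  })
}
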