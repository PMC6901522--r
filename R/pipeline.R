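#' Build and validate a pipeline run configuration
#'
#' A single structured configuration drives [run_pipeline()]. Paths are
#' stage inputs; the condition table maps peak-list files to pH/ligand
#' metadata. A serialized copy of the configuration is embedded in every
#' report so a run can be reproduced exactly.
#'
#' @param peaklists named character vector or list of peak-list paths
#'   (names are condition names), or `NULL`.
#' @param conditions data frame with columns `name` and `pH` (and
#'   optionally `ligand_conc`) matching `peaklists` names, or `NULL`.
#' @param reference_peak assignment label used for spectrum alignment
#'   (default the tryptophan indole-adjacent backbone amide `"W77N-H"`).
#' @param replicate_pair length-2 character vector naming the two
#'   replicate conditions whose perturbations define the Tukey fence, or
#'   `NULL` to use an explicit `first_bound`.
#' @param first_bound explicit first-bin bound in ppm (optional).
#' @param n_bins number of perturbation bins.
#' @param quartile_type quantile algorithm for the fence.
#' @param nu_N 15N Larmor frequency in Hz.
#' @param mass_calibration `c(slope, intercept)` in ns/kDa and ns.
#' @param region a [region_set()] for ensemble statistics.
#' @param ensemble_pdb path to a multi-model PDB (optional).
#' @param restraints path to a restraint table (optional).
#' @param smooth_window,smooth_polyorder Savitzky-Golay parameters.
#' @param relax_table path to a TSV of relaxation intensities with columns
#'   `label`, `experiment` (T1/T2), `delay_ms`, `intensity` (optional).
#' @param spectra_sample,spectra_buffer paths to two-column scans for the
#'   spectra stage (optional).
#' @param spectra_kind `"cd"` (baseline-subtract, molar ellipticity,
#'   smooth) or `"fluorescence"` (baseline-subtract, polynomial peak
#'   maximum).
#' @param conc_M,path_cm concentration (M) and pathlength (cm) for CD
#'   conversion.
#' @param seed integer seed for any simulated stage.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(peaklists = NULL, conditions = NULL,
                       reference_peak = "W77N-H",
                       replicate_pair = NULL, first_bound = NULL,
                       n_bins = 10L, quartile_type = 7L,
                       nu_N = 60.83e6, mass_calibration = c(0.6, 0),
                       region = region_set(), ensemble_pdb = NULL,
                       restraints = NULL, smooth_window = 11L,
                       smooth_polyorder = 3L, relax_table = NULL,
                       spectra_sample = NULL, spectra_buffer = NULL,
                       spectra_kind = c("cd", "fluorescence"),
                       conc_M = NULL, path_cm = 0.1, seed = 1L) {
  spectra_kind <- match.arg(spectra_kind)
  if (!is.null(peaklists)) {
    if (is.null(names(peaklists)) || any(!nzchar(names(peaklists))))
      stop("peaklists must be named by condition")
    missing <- !vapply(peaklists, file.exists, TRUE)
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(peaklists[missing]), collapse = ", "))
    if (!is.null(conditions) &&
        !all(names(peaklists) %in% conditions$name))
      stop("every peak list needs a row in the condition table")
  }
  stopifnot(n_bins >= 2L, nu_N > 0, length(mass_calibration) == 2L)
  structure(list(peaklists = peaklists, conditions = conditions,
                 reference_peak = reference_peak,
                 replicate_pair = replicate_pair,
                 first_bound = first_bound, n_bins = as.integer(n_bins),
                 quartile_type = quartile_type, nu_N = nu_N,
                 mass_calibration = mass_calibration, region = region,
                 ensemble_pdb = ensemble_pdb, restraints = restraints,
                 smooth_window = smooth_window,
                 smooth_polyorder = smooth_polyorder,
                 relax_table = relax_table,
                 spectra_sample = spectra_sample,
                 spectra_buffer = spectra_buffer,
                 spectra_kind = spectra_kind,
                 conc_M = conc_M, path_cm = path_cm,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_config_peaklists <- function(config) {
  pls <- lapply(names(config$peaklists), function(nm) {
    row <- if (is.null(config$conditions)) NULL
    else config$conditions[config$conditions$name == nm, ][1L, ]
    cond <- condition(nm,
                      pH = if (!is.null(row)) row$pH else NA_real_,
                      ligand_conc = if (!is.null(row) &&
                                        "ligand_conc" %in% names(row))
                        row$ligand_conc else NA_real_)
    read_peaklist(config$peaklists[[nm]], condition = cond)
  })
  names(pls) <- names(config$peaklists)
  pls
}

#' Run pipeline stages and write a report bundle
#'
#' Executes the requested stages against a validated configuration and
#' writes TSV/JSON outputs plus a `report.json` (embedding the
#' configuration and the per-stage output files) into `out_dir`. Runs are
#' deterministic given the configuration and seed. On a stage error the
#' remaining stages are skipped and the report is marked incomplete.
#'
#' @param config a [run_config()].
#' @param stages character subset of `c("simulate", "csp", "titrate",
#'   "relax", "ensemble", "spectra")`; the empty set validates the
#'   configuration and writes only the report.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config, stages = character(), out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "csp", "titrate", "relax", "ensemble", "spectra")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config_as_list(config), stages = list(),
                 complete = TRUE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  for (stage in intersect(known, stages)) {
    res <- tryCatch(
      switch(stage,
        simulate = {
          ds <- make_titration_dataset(titration_scenario(seed = config$seed))
          files <- character()
          for (nm in names(ds$peaklists)) {
            f <- file.path(out_dir, paste0("sim_pH", nm, ".list"))
            write_peaklist(ds$peaklists[[nm]], f)
            files <- c(files, f)
          }
          files <- c(files, tsv(ds$truth, "sim_truth.tsv"))
          list(files = files)
        },
        csp = {
          pls <- align_to_reference(load_config_peaklists(config),
                                    config$reference_peak)
          tab <- compute_csp(pls[[1L]], pls[[length(pls)]])
          ref <- NULL
          if (!is.null(config$replicate_pair))
            ref <- compute_csp(pls[[config$replicate_pair[1L]]],
                               pls[[config$replicate_pair[2L]]])
          binning <- bin_csp(tab, reference_values = ref,
                             n_bins = config$n_bins,
                             first_bound = config$first_bound,
                             quartile_type = config$quartile_type)
          out <- merge(as.data.frame(tab),
                       binning$map[, c("label", "bin")], by = "label")
          list(files = tsv(out[order(out$residue_number), ], "csp.tsv"),
               first_bound = binning$scheme$first_bound)
        },
        titrate = {
          pls <- align_to_reference(load_config_peaklists(config),
                                    config$reference_peak)
          curves <- build_titration_curves(pls)
          rows <- lapply(curves, function(cv) {
            fits <- list()
            for (m in c("cubic", "hh")) {
              f <- tryCatch(
                if (m == "cubic") fit_cubic_pka(cv) else fit_hh_pka(cv),
                error = function(e) NULL)
              if (!is.null(f))
                fits[[m]] <- data.frame(label = cv$label,
                                        method = f$method,
                                        pKa = round(f$pKa, 1),
                                        rmse = f$rmse,
                                        in_range = f$in_range)
            }
            do.call(rbind, fits)
          })
          list(files = tsv(do.call(rbind, rows), "pka_fits.tsv"))
        },
        relax = {
          if (is.null(config$relax_table))
            stop("relax stage needs 'relax_table' in the configuration")
          rt <- utils::read.delim(config$relax_table,
                                  stringsAsFactors = FALSE)
          need <- c("label", "experiment", "delay_ms", "intensity")
          if (!all(need %in% names(rt)))
            stop("relax_table must have columns: ",
                 paste(need, collapse = ", "))
          fits <- do.call(rbind, lapply(
            split(rt, list(rt$label, rt$experiment), drop = TRUE),
            function(g) {
              f <- fit_exponential(decay_series(
                g$delay_ms, g$intensity, label = g$label[1L],
                experiment = g$experiment[1L]))
              data.frame(label = g$label[1L],
                         residue_number = parse_assignment_label(
                           g$label[1L])$residue_number,
                         experiment = g$experiment[1L], T_ms = f$T,
                         rmse = f$rmse, ok = f$ok)
            }))
          fits <- fits[order(fits$experiment, fits$residue_number), ]
          mask <- region_residues(config$region)
          info <- list()
          for (ex in c("T1", "T2")) {
            sub <- fits[fits$experiment == ex & fits$ok, ]
            if (nrow(sub))
              info[[paste0("mean_", ex)]] <- average_over_mask(
                stats::setNames(sub$T_ms, sub$residue_number), mask)$mean
          }
          if (!is.null(info$mean_T1) && !is.null(info$mean_T2)) {
            tmb <- estimate_mass_from_tauc(
              estimate_tauc(info$mean_T1, info$mean_T2, config$nu_N),
              slope = config$mass_calibration[1L],
              intercept = config$mass_calibration[2L])
            info$tau_c_ns <- tmb$tau_c_ns_reported
            info$mw_kda <- tmb$mw_kda
            info$nu_N <- config$nu_N
          }
          f <- file.path(out_dir, "tumbling.json")
          jsonlite::write_json(info, f, auto_unbox = TRUE, digits = NA)
          list(files = c(tsv(fits, "relaxation_fits.tsv"), f),
               info = info)
        },
        ensemble = {
          files <- character(); info <- list()
          if (!is.null(config$ensemble_pdb)) {
            ens <- read_ensemble(config$ensemble_pdb)
            r <- ensemble_rmsd(ens, config$region)
            info$rmsd <- list(mean = r$mean, sd = r$sd,
                              n_atoms = r$n_atoms)
          }
          if (!is.null(config$restraints)) {
            cls <- classify_restraints(
              read_restraint_table(config$restraints))
            info$restraints <- unclass(cls)
          }
          f <- file.path(out_dir, "ensemble_stats.json")
          jsonlite::write_json(info, f, auto_unbox = TRUE, digits = NA)
          list(files = f, info = info)
        },
        spectra = {
          if (is.null(config$spectra_sample))
            stop("spectra stage needs 'spectra_sample' in the configuration")
          s <- read_xy_table(config$spectra_sample)
          if (!is.null(config$spectra_buffer))
            s <- subtract_baseline(s, read_xy_table(config$spectra_buffer))
          if (config$spectra_kind == "cd") {
            if (is.null(config$conc_M))
              stop("CD conversion needs 'conc_M' in the configuration")
            s <- to_molar_ellipticity(s, config$conc_M, config$path_cm)
            s <- savgol_smooth(s, config$smooth_window,
                               config$smooth_polyorder)
            f <- file.path(out_dir, "cd_molar_ellipticity.csv")
            write_xy_table(s, f)
            list(files = f)
          } else {
            pk <- polyfit_peak_max(s)
            f <- file.path(out_dir, "fluorescence_peak.json")
            jsonlite::write_json(
              list(wavelength_nm = pk$wavelength, degree = pk$degree,
                   rmse = pk$rmse, edge = pk$edge),
              f, auto_unbox = TRUE, digits = NA)
            list(files = f, info = list(wavelength_nm = pk$wavelength))
          }
        }
      ),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[stage]] <- list(status = "error",
                                     message = conditionMessage(res))
      report$complete <- FALSE
      warning("stage '", stage, "' failed: ", conditionMessage(res),
              "; remaining stages skipped")
      break
    }
    if (!is.null(res$files)) res$files <- basename(res$files)
    report$stages[[stage]] <- c(list(status = "ok"), res)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$region <- list(ranges = apply(config$region$ranges, 1L, identity,
                                    simplify = FALSE),
                     atom_selection = config$region$atom_selection,
                     include_O = config$region$include_O)
  out$conditions <- if (is.null(config$conditions)) NULL
  else as.list(config$conditions)
  out
}
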