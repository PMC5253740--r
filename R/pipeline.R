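#' Validate a pipeline configuration
#'
#' Checks stage names, required fields, and unit declarations before any
#' compute is started.
#'
#' @param config list (or path to a YAML file) with fields `seed`, `outdir`,
#'   `stages`, and per-stage parameter blocks.
#' @return The normalized config list, invisibly; errors name the offending
#'   field.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("synth", "hydro", "rigid_spectrum", "isf", "cumulant",
             "decompose", "modes", "cluster", "cv", "classify", "correct")
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("validation error: config lists no stages")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0)
    stop("validation error: unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outdir)) stop("validation error: outdir missing")
  if (is.null(config$seed)) config$seed <- 1L
  if ("correct" %in% config$stages) {
    cc <- config$correct
    if (is.null(cc$saxs_files) || is.null(cc$concentrations))
      stop("validation error: correct stage needs saxs_files and concentrations")
    if (is.null(cc$q_unit))
      stop("validation error: correct stage needs q_unit ('A^-1' or 'nm^-1')")
    if (is.null(cc$dls_d)) stop("validation error: correct stage needs dls_d")
  }
  if (any(c("isf", "decompose", "modes", "cluster", "cv") %in% config$stages) &&
      !("synth" %in% config$stages) && is.null(config$trajectory))
    stop("validation error: trajectory stages need either the synth stage ",
         "or an input trajectory (config$trajectory: dcd + pdb + dt)")
  invisible(config)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in fixed topological order on a run
#' directory: synthetic generation (toy tetramer + Brownian dynamics + OU
#' modes, one trajectory per configured temperature), hydrodynamic tensors,
#' rigid-body spectra, effective/internal/composed diffusion spectra,
#' per-residue fluctuations, conformational + kinetic networks, loop
#' collective variables, and the solution correction. Writes CSV/JSON/GEXF
#' outputs, a manifest (config, input hashes, package version), and a log.
#' Re-running with the same config and inputs reproduces the outputs.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$outdir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  seed <- as.integer(cfg$seed)
  qg <- cfg$q_grid %||% list(min = 0.04, max = 0.25, points = 10)
  Q_list <- seq(qg$min, qg$max, length.out = qg$points)
  n_orient <- cfg$n_orientations %||% 48
  fitw <- unlist(cfg$fit_window %||% c(0, 2))
  inputs <- character(0)

  systems <- list(); trajs <- list(); temps <- NULL

  if ("synth" %in% cfg$stages) {
    sy <- cfg$synth %||% list()
    temps <- sy$temperatures %||% c(283, 298, 313)
    tt <- toy_tetramer(sy$n_residues_per_subunit %||% 20,
                       loop_spec = list(n_loop = sy$n_loop_residues %||% 4,
                                        distances = sy$loop_distances %||%
                                          c(45, 60, 75)),
                       seed = seed)
    write_system_pdb(tt$system, file.path(cfg$outdir, "toy_tetramer_synthetic.pdb"))
    beads <- build_bead_model(tt$system, "one_bead_per_residue",
                              bead_radius = sy$bead_radius %||% 2.9)
    sigmas <- sy$mode_sigmas %||% seq(0.5, by = 0.65,
                                      length.out = length(temps))
    tau <- sy$mode_tau %||% 2.0
    n_frames <- sy$n_frames %||% 4000
    dt <- sy$dt %||% 0.05
    loop_sets <- lapply(c("A", "B", "C", "D"), function(ch)
      select_atoms(tt$system, chains = ch, resno_range = tt$loop_range))
    U <- localized_modes(tt$system$natoms, loop_sets)
    for (i in seq_along(temps)) {
      Tk <- temps[i]
      visc <- cfg$hydro$viscosity %||% d2o_viscosity(Tk)
      tens <- diffusion_tensor(beads, temperature = Tk, viscosity = visc)
      bd <- simulate_rigid_bd(tt$system, tens, n_frames, dt,
                              seed = derive_seed(seed, 1000L + i))
      tr <- add_internal_ou(bd, U, variances = rep(sigmas[i]^2, ncol(U)),
                            taus = rep(tau, ncol(U)),
                            seed = derive_seed(seed, 2000L + i))
      key <- as.character(Tk)
      systems[[key]] <- tt$system
      trajs[[key]] <- tr
      gt <- attr(tr, "ground_truth")
      jsonlite::write_json(
        list(temperature = Tk, D_T = tens$D_T, D_R = tens$D_R,
             mode_variances = gt$modes$variances, mode_taus = gt$modes$taus,
             seed = seed, n_frames = n_frames, dt = dt),
        file.path(cfg$outdir, sprintf("ground_truth_%sK.json", key)),
        digits = NA, auto_unbox = TRUE)
      say("synth: %s K, %d frames", key, n_frames)
    }
    cfg$toy <- tt
  } else if (!is.null(cfg$trajectory)) {
    tcfg <- cfg$trajectory
    sys <- system_from_pdb(tcfg$pdb, chains = tcfg$chains,
                           b_mode = tcfg$b_mode %||% "element")
    tr <- read_trajectory_dcd(tcfg$dcd, dt = tcfg$dt)
    inputs <- c(inputs, tcfg$pdb, tcfg$dcd)
    temps <- tcfg$temperature %||% NA_real_
    systems[[as.character(temps[1])]] <- sys
    trajs[[as.character(temps[1])]] <- tr
  }

  if ("hydro" %in% cfg$stages && length(systems) > 0) {
    sys <- systems[[1]]
    beads <- build_bead_model(sys, "one_bead_per_residue",
                              bead_radius = cfg$hydro$bead_radius %||% 2.9)
    for (key in names(systems)) {
      Tk <- as.numeric(key)
      visc <- cfg$hydro$viscosity %||% d2o_viscosity(Tk)
      tens <- diffusion_tensor(beads, temperature = Tk, viscosity = visc)
      if (!is.null(cfg$hydro$rescale))
        tens <- rescale_tensors(tens, cfg$hydro$rescale)
      write_tensors_json(tens, file.path(cfg$outdir,
                                         sprintf("tensors_%sK.json", key)))
      if ("rigid_spectrum" %in% cfg$stages) {
        sp <- rigid_body_spectrum(systems[[key]], tens, Q_list, n_orient)
        write_spectrum_csv(sp, file.path(cfg$outdir,
                                         sprintf("rigid_spectrum_%sK.csv", key)))
      }
      say("hydro: tensors at %s K (tr D_T/3 = %.3g A^2/ns)", key,
          mean(diag(tens$D_T)))
    }
  }

  for (key in names(trajs)) {
    tr <- trajs[[key]]; sys <- systems[[key]]
    if (any(c("isf", "cumulant") %in% cfg$stages)) {
      curves <- coherent_isf(tr, sys, Q_list, n_orientations = n_orient,
                             max_lag = fitw[2])
      write_isf_csv(curves, file.path(cfg$outdir, sprintf("isf_%sK.csv", key)))
      sp <- diffusion_spectrum(curves, fitw, temperature = as.numeric(key))
      write_spectrum_csv(sp, file.path(cfg$outdir,
                                       sprintf("effective_spectrum_%sK.csv", key)))
      say("isf/cumulant: %s K", key)
    }
    fitted <- NULL
    if (any(c("decompose", "modes", "cluster") %in% cfg$stages))
      fitted <- remove_rototranslation(tr)
    if ("decompose" %in% cfg$stages) {
      isp <- internal_spectrum(fitted, sys, Q_list, fitw,
                               n_orientations = n_orient, max_lag = fitw[2])
      write_spectrum_csv(isp, file.path(cfg$outdir,
                                        sprintf("internal_spectrum_%sK.csv", key)))
      gt <- attr(tr, "ground_truth")
      if (!is.null(gt$tensors)) {
        rsp <- rigid_body_spectrum(sys, gt$tensors, Q_list, n_orient)
        comp <- compose_total(rsp, isp)
        write_spectrum_csv(comp, file.path(cfg$outdir,
                                           sprintf("composed_spectrum_%sK.csv", key)))
      }
      say("decompose: %s K", key)
    }
    if ("modes" %in% cfg$stages) {
      ms <- pca_modes(fitted)
      msf <- msf_profile(fitted, sys)
      write.csv(msf, file.path(cfg$outdir, sprintf("msf_%sK.csv", key)),
                row.names = FALSE)
      say("modes: %s K (top eigenvalue %.3g A^2)", key, ms$values[1])
    }
    if ("cluster" %in% cfg$stages) {
      net <- leader_cluster(fitted, cutoff = cfg$cluster$cutoff %||% 1.5,
                            stride = cfg$cluster$stride %||% 1)
      net <- kinetic_network(net)
      export_network(net, file.path(cfg$outdir,
                                    sprintf("network_%sK.gexf", key)), "gexf")
      write_assignment_csv(net, file.path(cfg$outdir,
                                          sprintf("assignment_%sK.csv", key)))
      say("cluster: %s K (%d leaders, %d macrostates)", key,
          length(net$leaders), length(unique(net$macrostate)))
    }
    if ("cv" %in% cfg$stages && !is.null(cfg$toy)) {
      trace <- loop_cv(tr, sys, cfg$toy$loop_range, "A", "B")
      hd <- tryCatch(harmonic_diffusivity(trace), error = function(e) NULL)
      write_cv_csv(trace, file.path(cfg$outdir, sprintf("cv_AB_%sK.csv", key)))
      if (!is.null(hd))
        jsonlite::write_json(list(variance = hd$variance, tau = hd$tau,
                                  D = hd$D),
                             file.path(cfg$outdir,
                                       sprintf("cv_AB_%sK.json", key)),
                             digits = NA, auto_unbox = TRUE)
      say("cv: %s K", key)
    }
  }

  if ("correct" %in% cfg$stages) {
    cc <- cfg$correct
    series <- read_saxs_series(cc$saxs_files, cc$concentrations,
                               q_unit = cc$q_unit)
    inputs <- c(inputs, cc$saxs_files)
    s <- structure_factor_from_series(series, cc$target_C %||%
                                        max(cc$concentrations))
    write_structure_factor_csv(s, file.path(cfg$outdir, "structure_factor.csv"))
    specfile <- cc$spectrum_csv
    if (!is.null(specfile)) {
      df <- read.csv(specfile)
      inputs <- c(inputs, specfile)
      sp <- diffusion_spectrum_obj(df$Q, df$D, component = "effective")
      d0 <- apply_solution_correction(sp, s,
                                      hydro_anchor(cc$dls_d,
                                                   cc$anchor_window %||%
                                                     c(0.06, Inf)))
      write_spectrum_csv(d0, file.path(cfg$outdir, "d0_spectrum.csv"))
    }
    say("correct: S(Q) and D_0(Q) written")
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "toy")],
    inputs = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list(),
    package_version = as.character(utils::packageVersion("nsemd")))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(cfg$outdir)
}
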