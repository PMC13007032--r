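# FNV-1a hash of the canonical YAML text of the config (run provenance tag)
.config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.default_config <- function() {
  list(
    seed = 1L,
    temperature = 300,
    profile = list(form = "interfacial", depth = 26.5, xi_min = -4.7,
                   domain = c(-8, 12)),
    windows = list(centers = seq(-8, 12, length.out = 25),
                   force_constant = 41.84, n_samples = 5000, replicas = 2),
    wham = list(bin_width = 0.1, tol = 1e-6, max_iter = 1e5,
                plateau_range = c(6, 12)),
    slab = list(n_frames = 10, theta0 = 30, xi0 = 0),
    orientation = list(radius = 13, com_offset = 18,
                       xi_bins = seq(-2, 2, by = 1)),
    output_dir = "slabpmf_run"
  )
}

# recursive defaults merge: user values win
.merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) user[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && is.list(user[[k]]))
      user[[k]] <- .merge_config(user[[k]], defaults[[k]])
  }
  user
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes generate -> histogram -> WHAM -> plateau zeroing -> replica
#' combination on an analytic free-energy profile, then builds synthetic
#' slab/solvent frames, fits the interface densities, locates the Gibbs
#' dividing surfaces, and computes orientation and RMSD records. All tables
#' are written as TSV with YAML sidecars into the output directory, plus a
#' run log carrying the config hash, seeds, stage timings and residuals.
#'
#' @param config Path to a YAML config file, or a named list. Missing
#'   entries fall back to a documented demo configuration; `temperature`
#'   must be supplied by one of the two. All randomness derives from the
#'   single `seed` entry.
#' @return Invisible list with the in-memory stage results (`pmf`,
#'   `pmf_replicas`, `fits`, `surfaces`, `orientation`, `orientation_profile`,
#'   `rmsd`, `output_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$temperature))
    stop("config validation: `temperature` is required")
  cfg <- .merge_config(config, .default_config())
  hash <- .config_hash(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("slabpmf %s  config %s  seed %d",
                         as.character(utils::packageVersion("slabpmf")),
                         hash, as.integer(cfg$seed)))
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-12s %.2f s", name, tic() - t0))
    out
  }

  prof <- stage("profile", {
    pargs <- cfg$profile
    if (identical(pargs$form, "interfacial")) {
      pargs$form <- NULL
      do.call(interfacial_profile, pargs)
    } else do.call(analytic_profile, pargs)
  })
  centers <- as.numeric(unlist(cfg$windows$centers))

  replicas <- stage("wham", {
    lapply(seq_len(cfg$windows$replicas), function(r) {
      ws <- generate_window_set(prof, centers, cfg$windows$force_constant,
                                cfg$windows$n_samples, cfg$temperature,
                                seed = as.integer(cfg$seed) + 131L * r,
                                replica_id = r)
      edges <- seq(prof$domain[1], prof$domain[2], by = cfg$wham$bin_width)
      h <- build_histograms(ws, edges)
      p <- wham_solve(h, cfg$temperature, cfg$wham$tol, cfg$wham$max_iter)
      zero_by_plateau(p, cfg$wham$plateau_range)
    })
  })
  pmf <- if (length(replicas) >= 2) combine_replicas(replicas) else replicas[[1]]
  write_pmf(pmf, file.path(cfg$output_dir, "pmf.tsv"))

  slab_cfg <- cfg$slab
  n_frames <- slab_cfg$n_frames
  slab_cfg$n_frames <- NULL
  slab_args <- slab_cfg[names(slab_cfg) %in% names(formals(slab_system_spec))]
  slab_args$seed <- as.integer(cfg$seed) + 977L
  traj <- stage("slab", make_interface_trajectory(
    do.call(slab_system_spec, slab_args), n_frames = n_frames))

  fits <- stage("gds", {
    dp_pe <- density_profile(traj, "PE")
    dp_w <- density_profile(traj, "W")
    list(pe = fit_interface(dp_pe, "pe_slab"),
         solvent = fit_interface(dp_w, "solvent"),
         profile_pe = dp_pe, profile_w = dp_w)
  })
  surfaces <- gibbs_surfaces(fits$pe, fits$solvent)

  orient <- stage("orientation", orientation_records(
    traj, surfaces, radius = cfg$orientation$radius,
    com_offset = cfg$orientation$com_offset))
  oprof <- orientation_profile(orient[!is.na(orient$theta_deg), ],
                               as.numeric(unlist(cfg$orientation$xi_bins)))

  ref <- make_oriented_chain(slab_args$n_c %||% 8, 0, "extended")
  rmsd <- stage("rmsd", rmsd_records(traj, ref))

  wt <- function(df, name) write.table(df, file.path(cfg$output_dir, name),
                                       sep = "\t", quote = FALSE, row.names = FALSE)
  wt(orient, "orientation_records.tsv")
  wt(oprof, "orientation_profile.tsv")
  wt(rmsd, "rmsd.tsv")
  yaml::write_yaml(list(config_hash = hash, config = cfg,
                        gibbs_surfaces = list(z_lower = surfaces$z_lower,
                                              z_upper = surfaces$z_upper),
                        wham = list(iterations = replicas[[1]]$iterations,
                                    residual_kBT = replicas[[1]]$residual)),
                   file.path(cfg$output_dir, "run_meta.yaml"))
  writeLines(log_lines, file.path(cfg$output_dir, "run_log.txt"))
  invisible(list(pmf = pmf, pmf_replicas = replicas, fits = fits,
                 surfaces = surfaces, orientation = orient,
                 orientation_profile = oprof, rmsd = rmsd,
                 output_dir = cfg$output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
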