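# Experiment driver: build -> capped-force relaxation -> production run ->
# analysis, reproducible from (config, seed), with CSV/extended-XYZ outputs.

#' Full experiment configuration
#'
#' Bundles the build configuration, engine parameters, interaction matrix,
#' run lengths and analysis settings of one simulation experiment.
#'
#' @param build A [build_config()].
#' @param params A [dpd_params()].
#' @param interactions An [interaction_matrix()].
#' @param bonds A [bond_params()].
#' @param pre_equilibration_steps Capped-force relaxation steps.
#' @param production_steps Production run length (steps).
#' @param snapshot_interval Steps between trajectory frames.
#' @param thermo_interval Steps between temperature-log records.
#' @param burn_in Fraction of the production run discarded before
#'   analysis (default 0.5).
#' @param map_bin_width Density-map bin width (rc).
#' @param slab_thickness Density-map slab thickness (rc).
#' @param gr_bin_width g(r) bin width (rc).
#' @param profile_bin_width Radial-profile shell width (rc).
#' @param boundary_offset Free-drug boundary: outer half-maximum radius of
#'   the lipid profile plus this offset (rc).
#' @param rng_seed Master seed; the build and the noise stream derive from
#'   it.
#' @param output_dir Directory for output files, or `NULL` to skip writing.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(build = build_config(),
                              params = dpd_params(),
                              interactions = default_interaction_matrix(),
                              bonds = bond_params(),
                              pre_equilibration_steps = 1000,
                              production_steps = 1e5,
                              snapshot_interval = 2000,
                              thermo_interval = 1000,
                              burn_in = 0.5,
                              map_bin_width = 0.5,
                              slab_thickness = 2,
                              gr_bin_width = 0.1,
                              profile_bin_width = 0.25,
                              boundary_offset = 1,
                              rng_seed = 1L,
                              output_dir = NULL) {
  stopifnot(inherits(build, "build_config"), inherits(params, "dpd_params"),
            inherits(bonds, "bond_params"),
            pre_equilibration_steps >= 0, production_steps >= 1,
            snapshot_interval >= 1, burn_in >= 0, burn_in < 1,
            map_bin_width > 0, gr_bin_width > 0, profile_bin_width > 0)
  interactions <- interaction_matrix(interactions)
  build$rng_seed <- as.integer(rng_seed)
  structure(list(
    build = build, params = params, interactions = interactions,
    bonds = bonds,
    pre_equilibration_steps = as.integer(pre_equilibration_steps),
    production_steps = as.integer(production_steps),
    snapshot_interval = as.integer(snapshot_interval),
    thermo_interval = as.integer(thermo_interval),
    burn_in = burn_in, map_bin_width = map_bin_width,
    slab_thickness = slab_thickness, gr_bin_width = gr_bin_width,
    profile_bin_width = profile_bin_width,
    boundary_offset = boundary_offset,
    rng_seed = as.integer(rng_seed), output_dir = output_dir
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> seed %d, %d relax + %d production steps (frames every %d)\n",
    x$rng_seed, x$pre_equilibration_steps, x$production_steps,
    x$snapshot_interval))
  print(x$build)
  invisible(x)
}

# polynomial hash of the serialized config (hex string); identifies a run
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2L)
  h <- 0
  for (b in as.integer(raw)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Reduced desk-scale experiment preset
#'
#' A down-scaled vesicle system that preserves the study design at a size
#' tractable on one CPU: outer-leaflet radius 6.5 rc (about 640 lipids;
#' the 8-bead lipid makes a ~5 rc-thick membrane, so the radius is chosen
#' to leave an aqueous annulus inside the half-box for the profile-based
#' analysis), 25 capsaicin molecules and (by default) 5 chitosan 50-mers
#' in a cubic box of 18 rc at reduced density 3 (about 17500 beads).
#'
#' @param n_chitosan Number of chitosan chains.
#' @param sequence Chitosan sequence (`"S1"`, `"S2"`, or custom).
#' @param production_steps Production run length.
#' @param rng_seed Master seed.
#' @param ... Further arguments to [experiment_config()].
#' @return An `experiment_config`.
#' @export
reduced_experiment <- function(n_chitosan = 5, sequence = "S1",
                               production_steps = 1e5, rng_seed = 1L, ...) {
  experiment_config(
    build = build_config(
      vesicle_radius = 6.5, bilayer_thickness = 3.5, area_per_lipid = 1.0,
      n_capsaicin = 25, n_chitosan = n_chitosan, sequence = sequence,
      box = box_spec(18), rng_seed = rng_seed),
    production_steps = production_steps, rng_seed = rng_seed, ...)
}

#' Run one experiment end to end
#'
#' Builds the initial configuration, draws Maxwell-Boltzmann velocities,
#' relaxes it with capped forces, runs production DPD, and computes the
#' analysis battery: density maps for lecithin/chitosan/capsaicin, radial
#' density profiles, the three species-species PMFs
#' (lecithin-chitosan, lecithin-capsaicin, capsaicin-chitosan), the mean
#' vesicle diameter, and the encapsulation efficiency. Analysis uses the
#' frames after the burn-in fraction of the production run. Fully
#' reproducible from the configuration (which embeds the seed). When
#' `config$output_dir` is set, writes trajectory (extended XYZ),
#' temperature log, observables and a one-row summary as CSV, each stamped
#' with the config hash and seed.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return A list with elements `trajectory`, `analysis_frames`, `maps`,
#'   `profiles`, `pmf`, `summary` (one-row data.frame), `thermo`,
#'   `config`, `config_hash`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  stage <- "build"
  result <- tryCatch({
    say("[%s] building system", hash)
    state <- build_system(config$build)
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(config$rng_seed + 1L)
    state$velocities <- random_velocities(n_beads(state), config$params$kT)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

    stage <- "pre-equilibration"
    if (config$pre_equilibration_steps > 0L) {
      say("[%s] capped-force relaxation (%d steps)", hash,
          config$pre_equilibration_steps)
      state <- pre_equilibrate(state, config$interactions, config$bonds,
                               config$params,
                               n_steps = config$pre_equilibration_steps,
                               seed = config$rng_seed)
    }
    state$step <- 0L  # production clock starts after relaxation

    stage <- "production"
    say("[%s] production run (%d steps)", hash, config$production_steps)
    traj <- run_dpd(state, config$interactions, config$bonds, config$params,
                    n_steps = config$production_steps,
                    snapshot_interval = config$snapshot_interval,
                    thermo_interval = config$thermo_interval,
                    seed = config$rng_seed + 2L)

    stage <- "analysis"
    kT_dev <- abs(traj$thermo[, "kT"] / config$params$kT - 1)
    if (any(kT_dev > 0.1)) {
      warning(sprintf(
        "thermostat deviated >10%% from target kT at %d of %d log records",
        sum(kT_dev > 0.1), length(kT_dev)), call. = FALSE)
    }
    say("[%s] analysis", hash)
    analyze_experiment(traj, config, hash)
  }, error = function(e) {
    stop(sprintf("experiment stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$output_dir)) {
    write_experiment_outputs(result, config, hash)
  }
  result
}

# analysis battery on the post-burn-in frames
analyze_experiment <- function(traj, config, hash = config_hash(config)) {
  steps <- vapply(traj$frames, `[[`, numeric(1), "step")
  keep <- steps >= config$burn_in * config$production_steps
  atraj <- traj
  atraj$frames <- traj$frames[keep]

  maps <- list(
    lecithin = density_map_xy(atraj, c("L1", "L2", "L3"),
                              config$map_bin_width, config$slab_thickness),
    chitosan = density_map_xy(atraj, c("G", "A"),
                              config$map_bin_width, config$slab_thickness),
    capsaicin = density_map_xy(atraj, c("C1", "C2", "C3"),
                               config$map_bin_width, config$slab_thickness))

  profiles <- list(
    lecithin = radial_density_profile(atraj, c("L1", "L2", "L3"),
                                      dr = config$profile_bin_width),
    chitosan = radial_density_profile(atraj, c("G", "A"),
                                      dr = config$profile_bin_width),
    capsaicin = radial_density_profile(atraj, c("C1", "C2", "C3"),
                                       dr = config$profile_bin_width))

  pmf <- list()
  has_cs <- config$build$n_chitosan > 0L
  has_caps <- config$build$n_capsaicin > 0L
  if (has_cs) {
    pmf$lecithin_chitosan <- pmf_from_gr(
      pair_gr(atraj, "lecithin", "chitosan", config$gr_bin_width),
      kT = config$params$kT)
  }
  if (has_caps) {
    pmf$lecithin_capsaicin <- pmf_from_gr(
      pair_gr(atraj, "lecithin", "capsaicin", config$gr_bin_width),
      kT = config$params$kT)
  }
  if (has_cs && has_caps) {
    pmf$capsaicin_chitosan <- pmf_from_gr(
      pair_gr(atraj, "capsaicin", "chitosan", config$gr_bin_width),
      kT = config$params$kT)
  }

  size <- mean_diameter(atraj, config$build$box$length_scale,
                        dr = config$profile_bin_width)
  ee <- ee_sd <- boundary <- NA_real_
  if (has_caps) {
    free <- count_free_capsaicin(
      atraj, boundary_radius =
        half_max_outer_radius(profiles$lecithin) + config$boundary_offset)
    boundary <- free$boundary_radius
    ee_frames <- vapply(free$per_frame, function(f) {
      encapsulation_efficiency(config$build$n_capsaicin, f)
    }, numeric(1))
    ee <- mean(ee_frames)
    ee_sd <- stats::sd(ee_frames)
  }

  kT_prod <- if (is.null(traj$thermo)) NA_real_ else {
    traj$thermo[traj$thermo[, "step"] >=
                  config$burn_in * config$production_steps, "kT"]
  }

  summary <- data.frame(
    config_hash = hash,
    seed = config$rng_seed,
    n_chitosan = config$build$n_chitosan,
    concentration_mM = concentration_of(config$build$n_chitosan,
                                        config$build$box),
    n_capsaicin = config$build$n_capsaicin,
    size_nm = size$diameter_nm,
    size_sd_nm = size$sd_nm,
    size_rc = size$diameter_rc,
    ee_pct = ee,
    ee_sd_pct = ee_sd,
    free_boundary_rc = boundary,
    mean_kT = mean(kT_prod),
    stringsAsFactors = FALSE)

  list(trajectory = traj, analysis_frames = atraj, maps = maps,
       profiles = profiles, pmf = pmf, summary = summary,
       thermo = traj$thermo, config = config, config_hash = hash)
}

write_experiment_outputs <- function(result, config, hash) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(config$output_dir,
                   sprintf("run_%s_seed%d", hash, config$rng_seed))
  write_xyz(result$trajectory, paste0(pfx, ".xyz"))
  utils::write.csv(as.data.frame(result$thermo),
                   paste0(pfx, "_thermo.csv"), row.names = FALSE)
  for (nm in names(result$profiles)) {
    write_curve_csv(result$profiles[[nm]],
                    paste0(pfx, "_profile_", nm, ".csv"), config, hash)
  }
  for (nm in names(result$pmf)) {
    write_curve_csv(result$pmf[[nm]], paste0(pfx, "_pmf_", nm, ".csv"),
                    config, hash)
  }
  for (nm in names(result$maps)) {
    m <- result$maps[[nm]]
    con <- file(paste0(pfx, "_map_", nm, ".csv"), "w")
    writeLines(sprintf(
      "# density map (beads/rc^3); species=%s bin_width=%g slab=%g frames=%d config=%s seed=%d",
      nm, m$bin_width, m$slab_thickness, m$n_frames, hash, config$rng_seed),
      con)
    utils::write.table(m$grid, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  utils::write.csv(result$summary, paste0(pfx, "_summary.csv"),
                   row.names = FALSE)
  invisible(pfx)
}

write_curve_csv <- function(curve, path, config, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# reduced units; frames=%s config=%s seed=%d",
                     attr(curve, "n_frames"), hash, config$rng_seed), con)
  utils::write.table(as.data.frame(curve), con, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  close(con)
}

#' Chitosan concentration sweep preset
#'
#' The first study arm: capsaicin count fixed while the chitosan chain
#' count steps through 50, 100, 150, 200 (6, 12, 18, 24 mM in the
#' calibrated box at full scale).
#'
#' @param base An `experiment_config` to vary.
#' @param chain_counts Chain counts of the sweep.
#' @return A list of `experiment_config`s.
#' @export
cs_sweep_preset <- function(base = experiment_config(),
                            chain_counts = c(50L, 100L, 150L, 200L)) {
  lapply(chain_counts, function(n) {
    cfg <- base
    cfg$build$n_chitosan <- as.integer(n)
    cfg
  })
}

#' Acetylation-sequence preset
#'
#' The second study arm: two runs differing only in the chitosan
#' acetylation pattern (S1 quasi-random vs S2 blocky), at the lowest chain
#' count.
#'
#' @param base An `experiment_config` to vary.
#' @return A list of two `experiment_config`s.
#' @export
sequence_preset <- function(base = experiment_config()) {
  lapply(c("S1", "S2"), function(sq) {
    cfg <- base
    cfg$build$sequence <- builtin_sequence(sq)
    cfg
  })
}

#' Scale an experiment down (or keep it) proportionally
#'
#' Shrinks the box and vesicle linearly by `factor` and the molecule
#' counts by `factor^3`, so every species' molar concentration is
#' preserved (verified through [concentration_of()]).
#'
#' @param config An `experiment_config`.
#' @param factor Linear scale factor in (0, 1].
#' @return A scaled `experiment_config`.
#' @export
scale_preset <- function(config, factor) {
  stopifnot(inherits(config, "experiment_config"))
  if (!(factor > 0 && factor <= 1)) {
    stop("factor must be in (0, 1]", call. = FALSE)
  }
  b <- config$build
  r_new <- b$vesicle_radius * factor
  if (r_new < 4) {
    stop("scaled vesicle radius below minimum viable 4 rc", call. = FALSE)
  }
  b$vesicle_radius <- r_new
  # bilayer thickness is a material property and is not scaled
  b$box <- box_spec(b$box$lengths * factor, b$box$length_scale)
  b$n_capsaicin <- as.integer(round(b$n_capsaicin * factor^3))
  b$n_chitosan <- as.integer(round(b$n_chitosan * factor^3))
  config$build <- b
  config
}

#' Write an experiment config to a YAML file
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  b <- config$build
  lst <- list(
    build = list(
      vesicle_radius = b$vesicle_radius,
      bilayer_thickness = b$bilayer_thickness,
      area_per_lipid = b$area_per_lipid,
      n_capsaicin = b$n_capsaicin,
      n_chitosan = b$n_chitosan,
      sequence = format(b$sequence),
      box_lengths = b$box$lengths,
      length_scale = b$box$length_scale,
      target_density = b$target_density),
    params = unclass(config$params),
    bonds = unclass(config$bonds),
    interactions = apply(unclass(config$interactions), 1, as.list,
                         simplify = FALSE),
    run = list(
      pre_equilibration_steps = config$pre_equilibration_steps,
      production_steps = config$production_steps,
      snapshot_interval = config$snapshot_interval,
      thermo_interval = config$thermo_interval,
      burn_in = config$burn_in),
    analysis = list(
      map_bin_width = config$map_bin_width,
      slab_thickness = config$slab_thickness,
      gr_bin_width = config$gr_bin_width,
      profile_bin_width = config$profile_bin_width,
      boundary_offset = config$boundary_offset),
    rng_seed = config$rng_seed,
    output_dir = config$output_dir)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read an experiment config from a YAML file
#'
#' @param path Path to a YAML file written by [write_experiment_config()]
#'   (missing entries fall back to defaults).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  b <- lst$build
  bx <- box_spec(unlist(b$box_lengths),
                 if (is.null(b$length_scale)) 0.646 else b$length_scale)
  build <- build_config(
    vesicle_radius = b$vesicle_radius,
    bilayer_thickness = b$bilayer_thickness,
    area_per_lipid = b$area_per_lipid,
    n_capsaicin = b$n_capsaicin,
    n_chitosan = b$n_chitosan,
    sequence = as_chitosan_sequence(b$sequence),
    box = bx,
    target_density = if (is.null(b$target_density)) 3 else b$target_density,
    rng_seed = if (is.null(lst$rng_seed)) 1L else lst$rng_seed)
  p <- lst$params
  params <- dpd_params(gamma = p$gamma, kT = p$kT, dt = p$dt,
                       lambda = p$lambda, rc = p$rc)
  im <- if (is.null(lst$interactions)) {
    default_interaction_matrix()
  } else {
    m <- do.call(rbind, lapply(lst$interactions, unlist))
    dimnames(m) <- list(bead_types(), bead_types())
    interaction_matrix(m)
  }
  bp <- bond_params(lst$bonds$k_spring, lst$bonds$r0)
  rn <- lst$run
  an <- lst$analysis
  experiment_config(
    build = build, params = params, interactions = im, bonds = bp,
    pre_equilibration_steps = rn$pre_equilibration_steps,
    production_steps = rn$production_steps,
    snapshot_interval = rn$snapshot_interval,
    thermo_interval = rn$thermo_interval,
    burn_in = rn$burn_in,
    map_bin_width = an$map_bin_width,
    slab_thickness = an$slab_thickness,
    gr_bin_width = an$gr_bin_width,
    profile_bin_width = an$profile_bin_width,
    boundary_offset = an$boundary_offset,
    rng_seed = if (is.null(lst$rng_seed)) 1L else lst$rng_seed,
    output_dir = lst$output_dir)
}
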