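#' @useDynLib dpdvesicle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' DPD thermostat and integrator parameters
#'
#' Reduced-unit constants of the dissipative particle dynamics engine. The
#' dissipative strength `gamma` and the noise amplitude `sigma` are tied by
#' the fluctuation-dissipation relation `sigma^2 = 2 * gamma * kT`; a
#' `sigma` that violates it is rejected. Defaults are the standard choices
#' for a reduced-density-3 DPD fluid: `gamma = 4.5` (hence `sigma = 3` at
#' `kT = 1`), time step `dt = 0.03`, and velocity-prediction factor
#' `lambda = 0.65` of the modified velocity-Verlet scheme.
#'
#' @param gamma Dissipative strength (reduced).
#' @param kT Target temperature (reduced, default 1).
#' @param dt Integration time step (reduced).
#' @param lambda Velocity-prediction factor.
#' @param rc Interaction cutoff (reduced length unit, default 1).
#' @param sigma Noise amplitude; if `NULL`, set to `sqrt(2 * gamma * kT)`.
#' @return A `dpd_params` object.
#' @export
#' @examples
#' dpd_params()           # sigma = 3
dpd_params <- function(gamma = 4.5, kT = 1, dt = 0.03, lambda = 0.65,
                       rc = 1, sigma = NULL) {
  stopifnot(gamma >= 0, kT > 0, dt > 0, rc > 0, lambda > 0, lambda <= 1)
  sigma_fd <- sqrt(2 * gamma * kT)
  if (is.null(sigma)) {
    sigma <- sigma_fd
  } else if (abs(sigma^2 - 2 * gamma * kT) > 1e-10 * max(1, sigma_fd^2)) {
    stop("fluctuation-dissipation violated: sigma^2 must equal 2*gamma*kT ",
         sprintf("(got sigma = %g, expected %g)", sigma, sigma_fd),
         call. = FALSE)
  }
  structure(list(gamma = gamma, kT = kT, dt = dt, lambda = lambda,
                 rc = rc, sigma = sigma),
            class = "dpd_params")
}

#' @export
print.dpd_params <- function(x, ...) {
  cat(sprintf(
    "<dpd_params> gamma=%.3g sigma=%.3g kT=%.3g dt=%.3g lambda=%.3g rc=%.3g\n",
    x$gamma, x$sigma, x$kT, x$dt, x$lambda, x$rc))
  invisible(x)
}

#' Harmonic bond parameters
#'
#' All intramolecular bonds are harmonic springs
#' `F = -k_spring * (r - r0) * r_hat`. Defaults `k_spring = 100 kT/rc^2`,
#' `r0 = 0.7 rc` are typical bead-spring values for DPD lipids/polymers.
#'
#' @param k_spring Spring constant (kT/rc^2, >= 0).
#' @param r0 Equilibrium bond length (rc, >= 0).
#' @return A `bond_params` object.
#' @export
bond_params <- function(k_spring = 100, r0 = 0.7) {
  stopifnot(k_spring >= 0, r0 >= 0)
  structure(list(k_spring = k_spring, r0 = r0), class = "bond_params")
}

#' Conservative repulsion matrix between bead types
#'
#' Validates and labels a symmetric matrix of maximum conservative
#' repulsions `a_ij` (units kT/rc) over the nine bead types.
#'
#' @param a A symmetric numeric matrix with non-negative entries, either
#'   9 x 9 in canonical type order or named over a subset of types.
#' @return An `interaction_matrix` (a labelled 9 x 9 matrix).
#' @seealso [default_interaction_matrix()]
#' @export
interaction_matrix <- function(a) {
  types <- bead_types()
  a <- as.matrix(a)
  if (nrow(a) == length(types) && ncol(a) == length(types) &&
      (is.null(rownames(a)) || identical(rownames(a), types))) {
    dimnames(a) <- list(types, types)
  } else if (!is.null(rownames(a))) {
    stopifnot(all(rownames(a) %in% types), identical(rownames(a), colnames(a)))
    full <- unclass(default_interaction_matrix())
    full[rownames(a), colnames(a)] <- a
    a <- full
  } else {
    stop("interaction matrix must be 9 x 9 in canonical order, or named ",
         "over a subset of bead types", call. = FALSE)
  }
  if (any(a < 0)) stop("repulsion parameters must be >= 0", call. = FALSE)
  if (!isSymmetric(unname(a), tol = 1e-12)) {
    stop("interaction matrix must be symmetric", call. = FALSE)
  }
  structure(a, class = c("interaction_matrix", "matrix"))
}

#' Default conservative repulsion parameters
#'
#' A documented default `a_ij` table (kT/rc) for the nine bead types at
#' reduced density 3. Like-species repulsions follow the water
#' compressibility rule `a_ii = 25`. Cross terms encode the hydrophobic/
#' hydrophilic contrasts that drive the physics of the nanocapsule:
#' tail beads (`L3`, `C3`) strongly repel water (80), lecithin heads and
#' glucosamine are water-like, chitosan beads are mildly attracted to the
#' lecithin head relative to water (`G`-`L1` = 20, `A`-`L1` = 22) so the
#' polymer adsorbs on the vesicle surface, the acetylated monomer `A` is
#' slightly hydrophobic (`A`-`W` = 28, `A`-`A` = 23) allowing cooperative
#' association, and the capsaicin tail is compatible with the lipid tail
#' (`C3`-`L3` = 25) so the drug partitions into the membrane. Chitosan
#' beads repel lipid tails strongly (80/75): the polymer coats but does not
#' enter the membrane. All entries can be overridden via
#' [interaction_matrix()] or the experiment config.
#'
#' @return An `interaction_matrix`.
#' @export
default_interaction_matrix <- function() {
  types <- bead_types()
  a <- matrix(25, 9, 9, dimnames = list(types, types))
  set <- function(i, j, v) {
    a[i, j] <<- v
    a[j, i] <<- v
  }
  # water contrasts
  set("L2", "W", 45); set("L3", "W", 80)
  set("C1", "W", 30); set("C2", "W", 60); set("C3", "W", 80)
  set("A", "W", 28)
  # lecithin internal / cross
  set("L1", "L3", 80); set("L2", "L3", 30)
  # capsaicin internal / lecithin cross
  set("C1", "C3", 50)
  set("L1", "C2", 45); set("L1", "C3", 60)
  set("L2", "C1", 30); set("L2", "C2", 30); set("L2", "C3", 40)
  set("L3", "C1", 50); set("L3", "C2", 30)  # C3-L3 stays 25
  # chitosan: surface-active, membrane-excluded
  set("G", "L1", 20); set("A", "L1", 22)
  set("G", "L2", 30); set("A", "L2", 30)
  set("G", "L3", 80); set("A", "L3", 75)
  set("G", "C1", 26); set("A", "C1", 24)
  set("G", "C2", 50); set("A", "C2", 45)
  set("G", "C3", 80); set("A", "C3", 75)
  set("A", "A", 23)
  interaction_matrix(a)
}

# ---------------------------------------------------------------------------
# Pure-R pairwise force formulas (reference implementations; the compiled
# core is cross-checked against these in the tests)
# ---------------------------------------------------------------------------

#' Conservative DPD pair force
#'
#' Soft linear repulsion `F = a_ij * (1 - r/rc) * r_hat` for `r < rc`, zero
#' beyond the cutoff, acting on particle i for minimum-image displacement
#' `r_vec = x_i - x_j`. A coincident pair (r = 0) gives zero force: the
#' direction is undefined and the event has measure zero under soft
#' potentials.
#'
#' @param a_ij Maximum repulsion (kT/rc).
#' @param r_vec Minimum-image displacement 3-vector.
#' @param rc Cutoff (default 1).
#' @return Force 3-vector on particle i.
#' @export
conservative_pair_force <- function(a_ij, r_vec, rc = 1) {
  r <- sqrt(sum(r_vec^2))
  if (r >= rc || r < 1e-12) return(c(0, 0, 0))
  a_ij * (1 - r / rc) * r_vec / r
}

#' Dissipative plus random DPD pair force
#'
#' The pairwise thermostat: `F_D = -gamma * w_D(r) * (r_hat . v_rel) *
#' r_hat` with `w_D = (1 - r/rc)^2`, and `F_R = sigma * w_R(r) * theta *
#' r_hat / sqrt(dt)` with `w_R = (1 - r/rc)`, so that `w_D = w_R^2` and
#' `sigma^2 = 2 * gamma * kT` satisfy the fluctuation-dissipation theorem.
#' `theta` must be a symmetric unit-variance variate shared by the pair
#' (`theta_ij = theta_ji`).
#'
#' @param params A [dpd_params()] object.
#' @param r_vec Minimum-image displacement 3-vector (`x_i - x_j`).
#' @param v_rel Relative velocity 3-vector (`v_i - v_j`).
#' @param noise Unit-variance symmetric random variate for this pair.
#' @return Combined force 3-vector on particle i.
#' @export
dissipative_random_pair_force <- function(params, r_vec, v_rel, noise) {
  stopifnot(inherits(params, "dpd_params"))
  r <- sqrt(sum(r_vec^2))
  if (r >= params$rc || r < 1e-12) return(c(0, 0, 0))
  e <- r_vec / r
  w <- 1 - r / params$rc
  fd <- -params$gamma * w^2 * sum(e * v_rel)
  fr <- params$sigma * w * noise / sqrt(params$dt)
  (fd + fr) * e
}

#' Harmonic bond force
#'
#' @param bp A [bond_params()] object.
#' @param r_vec Displacement 3-vector (`x_i - x_j`).
#' @return Restoring force 3-vector on particle i.
#' @export
bond_force <- function(bp, r_vec) {
  stopifnot(inherits(bp, "bond_params"))
  r <- sqrt(sum(r_vec^2))
  if (r < 1e-12) return(c(0, 0, 0))
  -bp$k_spring * (r - bp$r0) * r_vec / r
}

# ---------------------------------------------------------------------------
# Simulation state
# ---------------------------------------------------------------------------

#' Construct a simulation state
#'
#' The full particle state of a periodic DPD system in reduced units.
#'
#' @param positions N x 3 matrix of coordinates (wrapped into the box).
#' @param box Length-3 vector of box edges (rc).
#' @param species Character vector of bead type labels (length N).
#' @param molecule_id Integer vector assigning each bead to a molecule.
#' @param molecule_species Character vector naming the species of each
#'   molecule (indexed by molecule id), e.g. `"lecithin"`.
#' @param bonds M x 2 integer matrix of bonded bead pairs (1-based global
#'   indices), or `NULL`.
#' @param velocities N x 3 matrix; defaults to zero.
#' @param images N x 3 integer matrix of periodic image counters
#'   (unwrapped position = positions + images * box); defaults to zero.
#' @param step Step counter (default 0).
#' @return A `simulation_state` object.
#' @export
simulation_state <- function(positions, box, species, molecule_id,
                             molecule_species = NULL, bonds = NULL,
                             velocities = NULL, images = NULL, step = 0L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(box) == 3L, all(box > 0),
            length(species) == n, length(molecule_id) == n)
  bad <- setdiff(unique(species), bead_types())
  if (length(bad) > 0L) {
    stop("unknown bead type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(velocities)) velocities <- matrix(0, n, 3L)
  if (is.null(images)) images <- matrix(0L, n, 3L)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L && (any(bonds < 1L) || any(bonds > n))) {
    stop("bond index out of range", call. = FALSE)
  }
  # wrap into [0, L)
  for (d in 1:3) {
    shift <- floor(positions[, d] / box[d])
    positions[, d] <- positions[, d] - shift * box[d]
    images[, d] <- images[, d] + as.integer(shift)
  }
  structure(list(
    positions = positions,
    velocities = as.matrix(velocities),
    images = images,
    species = species,
    molecule_id = as.integer(molecule_id),
    molecule_species = molecule_species,
    bonds = bonds,
    box = as.numeric(box),
    step = as.integer(step),
    forces = NULL
  ), class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf(
    "<simulation_state> %d beads, %d molecules, %d bonds, box %.4g x %.4g x %.4g rc, step %d\n",
    nrow(x$positions), length(unique(x$molecule_id)), nrow(x$bonds),
    x$box[1], x$box[2], x$box[3], x$step))
  tab <- table(x$species)
  cat("  beads:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Bead count of a state
#' @param state A `simulation_state`.
#' @return Integer bead count.
#' @export
n_beads <- function(state) nrow(state$positions)

#' Overall reduced number density of a state
#' @param state A `simulation_state`.
#' @return Beads per rc^3.
#' @export
number_density <- function(state) n_beads(state) / prod(state$box)

#' Maxwell-Boltzmann velocities at a target temperature
#'
#' Draws velocities from a normal distribution at reduced temperature `kT`
#' (unit masses) and removes the center-of-mass drift.
#'
#' @param n Number of beads.
#' @param kT Reduced temperature.
#' @return N x 3 velocity matrix. Uses R's RNG stream (`set.seed()` for
#'   reproducibility).
#' @export
random_velocities <- function(n, kT = 1) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT)), n, 3L)
  sweep(v, 2L, colMeans(v))
}

#' Instantaneous kinetic temperature
#'
#' `kT = sum(m v^2) / (3 (N - 1))` with the center-of-mass velocity removed,
#' so a uniform drift does not register as heat.
#'
#' @param state A `simulation_state` (or an N x 3 velocity matrix).
#' @return Reduced temperature.
#' @export
instantaneous_temperature <- function(state) {
  v <- if (inherits(state, "simulation_state")) state$velocities else as.matrix(state)
  if (nrow(v) < 2L) stop("temperature requires at least 2 beads", call. = FALSE)
  cpp_temperature(v)
}

#' Neighbour pairs within the cutoff
#'
#' Enumerates all minimum-image pairs with separation below `rc`, using the
#' same cell-list search as the force loop (with an all-pairs fallback when
#' any box side is below `3 rc`).
#'
#' @param positions N x 3 coordinate matrix (or a `simulation_state`).
#' @param box Length-3 box vector (ignored when a state is given).
#' @param rc Cutoff distance.
#' @return A two-column integer matrix of 1-based pairs with `i < j`,
#'   ordered lexicographically.
#' @export
neighbor_pairs <- function(positions, box = NULL, rc = 1) {
  if (inherits(positions, "simulation_state")) {
    box <- positions$box
    positions <- positions$positions
  }
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) return(matrix(integer(0), ncol = 2L))
  stopifnot(length(box) == 3L, all(box >= rc))
  p <- cpp_neighbor_pairs(positions, as.numeric(box), rc)
  p[order(p[, 1L], p[, 2L]), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Integration drivers
# ---------------------------------------------------------------------------

run_core <- function(state, im, bp, params, n_steps, seed, snapshot_every,
                     thermo_every, force_cap) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(params, "dpd_params"),
            inherits(bp, "bond_params"), n_steps >= 1)
  im <- interaction_matrix(im)
  type_idx <- match(state$species, bead_types()) - 1L
  bonds0 <- state$bonds - 1L
  f0 <- if (is.null(state$forces)) matrix(0, 0L, 3L) else state$forces
  cpp_run_dpd(
    pos = state$positions, vel = state$velocities, images = state$images,
    types = type_idx, aij = unclass(im), bonds = bonds0,
    bond_k = bp$k_spring, bond_r0 = bp$r0, box = state$box, rc = params$rc,
    gamma = params$gamma, sigma = params$sigma, lambda = params$lambda,
    dt = params$dt, n_steps = as.integer(n_steps),
    step0 = state$step, seed = as.numeric(seed),
    snapshot_every = as.integer(snapshot_every),
    thermo_every = as.integer(thermo_every), force_cap = force_cap,
    f0 = f0)
}

update_state <- function(state, res) {
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$images <- res$images
  state$forces <- res$forces
  state$step <- res$step
  state
}

#' Advance a state by n integration steps
#'
#' Modified velocity-Verlet with prediction factor `lambda`: positions are
#' advanced with the current forces, velocities are predicted, forces
#' recomputed at the new positions/predicted velocities, then velocities
#' corrected with the force average. The per-pair random variate is
#' counter-based on `(seed, step, i, j)`, so a run is bit-reproducible and a
#' restart from a checkpointed state (which carries its forces) continues
#' the unbroken trajectory exactly.
#'
#' @param state A `simulation_state`.
#' @param im Interaction matrix (see [interaction_matrix()]).
#' @param bp Bond parameters.
#' @param params DPD parameters.
#' @param n_steps Number of steps (>= 1).
#' @param seed Integer noise seed.
#' @param force_cap Positive value clamps each bead's net force magnitude
#'   (capped-force relaxation); 0 disables.
#' @return The advanced `simulation_state`.
#' @export
integrate_steps <- function(state, im, bp, params, n_steps, seed = 1,
                            force_cap = 0) {
  res <- run_core(state, im, bp, params, n_steps, seed,
                  snapshot_every = 0L, thermo_every = 0L,
                  force_cap = force_cap)
  update_state(state, res)
}

#' Capped-force pre-equilibration
#'
#' Relaxes a freshly built configuration by integrating with each bead's
#' net force clamped to `force_cap`, removing any pathological initial
#' stresses without large displacements.
#'
#' @inheritParams integrate_steps
#' @param n_steps Number of relaxation steps (default 1000).
#' @param force_cap Clamp on the net per-bead force magnitude (default 50).
#' @return The relaxed `simulation_state`.
#' @export
pre_equilibrate <- function(state, im, bp, params, n_steps = 1000, seed = 1,
                            force_cap = 50) {
  stopifnot(force_cap > 0)
  integrate_steps(state, im, bp, params, n_steps, seed, force_cap = force_cap)
}

#' Run a DPD simulation and record a trajectory
#'
#' Advances the state for `n_steps`, recording a frame every
#' `snapshot_interval` steps (the entry state is frame 0) and a
#' thermodynamic log record (step, kT, total momentum, max net force) every
#' `thermo_interval` steps. Observer callbacks, if given, are invoked as
#' `fn(state, step)` for every recorded frame.
#'
#' @inheritParams integrate_steps
#' @param snapshot_interval Steps between trajectory frames.
#' @param thermo_interval Steps between log records (default 1000).
#' @param observers List of functions `fn(state, step)`.
#' @return A `dpd_trajectory` object; the final state is in `$state`.
#' @export
run_dpd <- function(state, im, bp = bond_params(), params = dpd_params(),
                    n_steps = 1000, snapshot_interval = 100,
                    thermo_interval = 1000, observers = list(), seed = 1) {
  res <- run_core(state, im, bp, params, n_steps, seed,
                  snapshot_every = as.integer(snapshot_interval),
                  thermo_every = as.integer(thermo_interval), force_cap = 0)
  final <- update_state(state, res)
  traj <- structure(list(
    frames = res$frames,
    box = state$box,
    species = state$species,
    molecule_id = state$molecule_id,
    molecule_species = state$molecule_species,
    bonds = state$bonds,
    thermo = res$thermo,
    state = final,
    seed = seed
  ), class = "dpd_trajectory")
  if (length(observers) > 0L) {
    for (fr in traj$frames) {
      snap <- final
      snap$positions <- fr$positions
      snap$velocities <- fr$velocities
      snap$images <- fr$images
      snap$step <- fr$step
      for (obs in observers) obs(snap, fr$step)
    }
  }
  traj
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  steps <- vapply(x$frames, function(f) f$step, numeric(1))
  cat(sprintf(
    "<dpd_trajectory> %d frames (steps %s..%s), %d beads, box %.4g x %.4g x %.4g rc\n",
    length(x$frames), if (length(steps)) min(steps) else NA,
    if (length(steps)) max(steps) else NA,
    length(x$species), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `dpd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a simulation state
#'
#' @param traj A `dpd_trajectory`.
#' @param i Frame index (1-based).
#' @return A `simulation_state` (without forces; not suitable for exact
#'   restart unless it is the final frame, for which use `traj$state`).
#' @export
trajectory_frame <- function(traj, i) {
  fr <- traj$frames[[i]]
  st <- simulation_state(
    positions = fr$positions, box = traj$box, species = traj$species,
    molecule_id = traj$molecule_id, molecule_species = traj$molecule_species,
    bonds = traj$bonds, velocities = fr$velocities, images = fr$images,
    step = fr$step)
  st
}
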