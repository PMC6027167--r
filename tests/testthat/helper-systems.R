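# Shared fixture builders (all generated in code, reduced units).

# homogeneous solvent fluid at a given density
solvent_fluid <- function(L, density = 3, kT = 1, seed = 1) {
  set.seed(seed)
  n <- round(density * L^3)
  pos <- matrix(runif(3 * n) * L, n, 3)
  st <- simulation_state(pos, rep(L, 3), rep("W", n), seq_len(n),
                         molecule_species = rep("water", n))
  st$velocities <- random_velocities(n, kT)
  st
}

# brute-force O(N^2) minimum-image pair enumeration (oracle)
brute_force_pairs <- function(pos, box, rc = 1) {
  n <- nrow(pos)
  out <- list()
  for (i in seq_len(max(0, n - 1))) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (k in 1:3) d[, k] <- d[, k] - round(d[, k] / box[k]) * box[k]
    hit <- which(rowSums(d^2) < rc^2)
    if (length(hit) > 0) out[[length(out) + 1]] <- cbind(i, i + hit)
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# flat periodic bilayer patch in the xy plane, midplane at z = Lz/2
bilayer_patch <- function(Lx, Ly, Lz, area_per_lipid = 1.05,
                          bond_len = 0.7, density = 3, kT = 1, seed = 1) {
  set.seed(seed)
  topo <- lecithin_topology()
  n_side <- round(sqrt(Lx * Ly / area_per_lipid))
  xg <- (seq_len(n_side) - 0.5) / n_side * Lx
  yg <- (seq_len(n_side) - 0.5) / n_side * Ly
  mid <- Lz / 2
  ms <- dpdvesicle:::empty_molecule_set()
  depths <- dpdvesicle:::topology_depths(topo)
  for (leaf in c(+1, -1)) {  # +1: heads above midplane
    z_head <- mid + leaf * 4 * bond_len
    for (xi in xg) for (yi in yg) {
      nb <- length(topo$beads)
      pos <- matrix(0, nb, 3)
      for (b in seq_len(nb)) {
        off <- if (depths$branch[b] > 0) {
          0.25 * c(cos(pi * depths$branch[b]), sin(pi * depths$branch[b]))
        } else c(0, 0)
        pos[b, ] <- c(xi + off[1], yi + off[2],
                      z_head - leaf * depths$depth[b] * bond_len)
      }
      ms <- dpdvesicle:::add_molecule(ms, pos, topo)
    }
  }
  ms <- fill_solvent(ms, box_spec(c(Lx, Ly, Lz)), density)
  st <- simulation_state(ms$positions, c(Lx, Ly, Lz), ms$species,
                         ms$molecule_id, ms$molecule_species, ms$bonds)
  st$velocities <- random_velocities(n_beads(st), kT)
  st
}

# spherical shell of beads at radius R around the box center (delta-shell
# fixture for radial profiles); species defaults to lecithin head beads so
# the shell also defines the vesicle center
delta_shell_state <- function(R, n = 500, L = 4 * R, species = "L1") {
  u <- dpdvesicle:::fibonacci_sphere(n)
  pos <- sweep(R * u, 2, rep(L / 2, 3), `+`)
  simulation_state(pos, rep(L, 3), rep(species, n), seq_len(n),
                   molecule_species = rep("lecithin", n))
}

# tiny but complete vesicle experiment (seconds, for pipeline smoke tests)
tiny_experiment <- function(seed = 1, production_steps = 400, ...) {
  experiment_config(
    build = build_config(
      vesicle_radius = 4.5, bilayer_thickness = 2.8, area_per_lipid = 1.2,
      n_capsaicin = 5, n_chitosan = 1, box = box_spec(13), rng_seed = seed),
    pre_equilibration_steps = 200,
    production_steps = production_steps,
    snapshot_interval = 100,
    thermo_interval = 100,
    rng_seed = seed, ...)
}
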