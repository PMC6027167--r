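AVOGADRO <- 6.02214076e23

#' Periodic box specification
#'
#' A periodic orthorhombic box in reduced length units (the cutoff
#' `rc = 1`), plus the physical mapping `length_scale` in nm per rc used to
#' convert reduced results to nanometers and to relate bead counts to molar
#' concentrations. The default `length_scale = 0.646` nm is the common
#' three-waters-per-bead DPD mapping at reduced density 3.
#'
#' @param lengths Length-3 vector of box edges (rc), all > 0.
#' @param length_scale nm per rc.
#' @return A `box_spec` object.
#' @export
box_spec <- function(lengths, length_scale = 0.646) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 1L) lengths <- rep(lengths, 3L)
  stopifnot(length(lengths) == 3L, all(lengths > 0), length_scale > 0)
  structure(list(lengths = lengths, length_scale = length_scale),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box_spec> %.4g x %.4g x %.4g rc (%.4g nm/rc, V = %.4g nm^3)\n",
              x$lengths[1], x$lengths[2], x$lengths[3], x$length_scale,
              box_volume_nm3(x)))
  invisible(x)
}

#' Physical box volume in nm^3
#' @param box A `box_spec`.
#' @return Volume in nm^3.
#' @export
box_volume_nm3 <- function(box) {
  stopifnot(inherits(box, "box_spec"))
  prod(box$lengths) * box$length_scale^3
}

#' Box volume that realizes a chain count at a molar concentration
#'
#' The physical volume for which `n_chains` solute molecules correspond to
#' the molar concentration `concentration`: `V = n / (N_A * c)`. Used to
#' calibrate the simulation box so that the modeled chain counts map onto
#' stated concentrations (e.g. 50 chitosan chains at 6 mM fix one box in
#' which 100, 150, 200 chains are 12, 18, 24 mM).
#'
#' @param n_chains Number of molecules (> 0).
#' @param concentration Concentration in mM (> 0).
#' @return Volume in nm^3.
#' @export
#' @examples
#' volume_from_calibration(50, 6)   # ~1.384e4 nm^3
volume_from_calibration <- function(n_chains, concentration) {
  stopifnot(n_chains > 0, concentration > 0)
  moles <- n_chains / AVOGADRO
  litres <- moles / (concentration * 1e-3)
  litres * 1e24  # 1 L = 1e24 nm^3
}

#' Molar concentration of a chain count in a box
#'
#' Inverse of [volume_from_calibration()]: `c = n / (N_A * V)`, reported
#' in mM.
#'
#' @param n_chains Number of molecules (>= 0).
#' @param box A `box_spec` (its physical volume is used).
#' @return Concentration in mM.
#' @export
concentration_of <- function(n_chains, box) {
  v_nm3 <- box_volume_nm3(box)
  if (v_nm3 <= 0) stop("box volume must be positive", call. = FALSE)
  stopifnot(n_chains >= 0)
  litres <- v_nm3 * 1e-24
  (n_chains / AVOGADRO) / litres * 1e3
}

#' Default calibrated box
#'
#' The cubic box whose physical volume makes 50 solute chains correspond to
#' 6 mM (hence 100/150/200 chains to 12/18/24 mM), converted to reduced
#' units via `length_scale`.
#'
#' @param length_scale nm per rc.
#' @return A `box_spec`.
#' @export
calibrated_box <- function(length_scale = 0.646) {
  v_nm3 <- volume_from_calibration(50, 6)
  edge_nm <- v_nm3^(1 / 3)
  box_spec(rep(edge_nm / length_scale, 3L), length_scale)
}

#' Build configuration for a vesicle-plus-solutes system
#'
#' @param vesicle_radius Outer-leaflet head radius R_out (rc).
#' @param bilayer_thickness Head-to-head bilayer thickness (rc);
#'   inner-leaflet heads sit at `R_out - bilayer_thickness`.
#' @param area_per_lipid Area per lipid on a leaflet head sphere (rc^2).
#' @param n_capsaicin Number of capsaicin molecules.
#' @param n_chitosan Number of chitosan chains.
#' @param sequence Chitosan sequence: `"S1"`, `"S2"`, or a
#'   `chitosan_sequence`.
#' @param box A `box_spec`; defaults to the concentration-calibrated box.
#' @param target_density Total bead number density (beads per rc^3).
#' @param rng_seed Integer seed controlling all build randomness.
#' @return A `build_config` object.
#' @export
build_config <- function(vesicle_radius = 14, bilayer_thickness = 3.5,
                         area_per_lipid = 1.25, n_capsaicin = 250,
                         n_chitosan = 50, sequence = "S1",
                         box = calibrated_box(), target_density = 3,
                         rng_seed = 1L) {
  stopifnot(inherits(box, "box_spec"))
  if (!(vesicle_radius > bilayer_thickness && bilayer_thickness > 0)) {
    stop("need vesicle_radius > bilayer_thickness > 0", call. = FALSE)
  }
  stopifnot(area_per_lipid > 0, n_capsaicin >= 0, n_chitosan >= 0,
            target_density > 0)
  if (vesicle_radius + 1 > min(box$lengths) / 2) {
    stop("vesicle does not fit in the box with >= 1 rc clearance",
         call. = FALSE)
  }
  if (is.character(sequence)) sequence <- builtin_sequence(sequence)
  sequence <- as_chitosan_sequence(sequence)
  structure(list(
    vesicle_radius = vesicle_radius,
    bilayer_thickness = bilayer_thickness,
    area_per_lipid = area_per_lipid,
    n_capsaicin = as.integer(n_capsaicin),
    n_chitosan = as.integer(n_chitosan),
    sequence = sequence,
    box = box,
    target_density = target_density,
    rng_seed = as.integer(rng_seed)
  ), class = "build_config")
}

#' @export
print.build_config <- function(x, ...) {
  cat(sprintf(
    paste0("<build_config> R_out=%.3g rc, thickness=%.3g rc, a_pl=%.3g rc^2, ",
           "%d capsaicin, %d chitosan (%d-mer, DA %.2f), density %.3g\n"),
    x$vesicle_radius, x$bilayer_thickness, x$area_per_lipid, x$n_capsaicin,
    x$n_chitosan, length(x$sequence), degree_of_acetylation(x$sequence),
    x$target_density))
  print(x$box)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Molecule set accumulator (internal)
# ---------------------------------------------------------------------------

empty_molecule_set <- function() {
  list(positions = matrix(numeric(0), ncol = 3L), species = character(0),
       molecule_id = integer(0), molecule_species = character(0),
       bonds = matrix(integer(0), ncol = 2L))
}

add_molecule <- function(ms, positions, topo) {
  offset <- nrow(ms$positions)
  mol_id <- length(ms$molecule_species) + 1L
  ms$positions <- rbind(ms$positions, positions)
  ms$species <- c(ms$species, topo$beads)
  ms$molecule_id <- c(ms$molecule_id, rep(mol_id, length(topo$beads)))
  ms$molecule_species <- c(ms$molecule_species, topo$species)
  if (nrow(topo$bonds) > 0L) {
    ms$bonds <- rbind(ms$bonds, topo$bonds + offset + 1L)  # to 1-based global
  }
  ms
}

merge_molecule_sets <- function(a, b) {
  offset <- nrow(a$positions)
  mol_offset <- length(a$molecule_species)
  a$positions <- rbind(a$positions, b$positions)
  a$species <- c(a$species, b$species)
  a$molecule_id <- c(a$molecule_id, b$molecule_id + mol_offset)
  a$molecule_species <- c(a$molecule_species, b$molecule_species)
  if (nrow(b$bonds) > 0L) a$bonds <- rbind(a$bonds, b$bonds + offset)
  a
}

# Fibonacci sphere: m approximately evenly spread unit vectors (deterministic)
fibonacci_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Per-bead radial depth (bond steps from the head bead) and a tail index
# used to fan multiple tails tangentially.
topology_depths <- function(topo) {
  nb <- length(topo$beads)
  adj <- vector("list", nb)
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[k, 1L] + 1L
    j <- topo$bonds[k, 2L] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  depth <- rep(NA_integer_, nb)
  branch <- rep(0L, nb)
  depth[1L] <- 0L
  queue <- 1L
  nb_branch <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        if (v == 2L) {  # chains rooted at the neck bead fan out separately
          nb_branch <- nb_branch + 1L
          branch[w] <- nb_branch
        } else {
          branch[w] <- branch[v]
        }
        queue <- c(queue, w)
      }
    }
  }
  list(depth = depth, branch = branch)
}

# Place one lipid along the (outward) radial unit vector u, head at radius R.
# direction = -1: beads at decreasing radius (outer leaflet); +1: increasing
# (inner leaflet). Tails are fanned tangentially so they do not coincide.
place_lipid <- function(topo, center, u, R, direction, bond_len, depths) {
  # tangent basis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  nb <- length(topo$beads)
  pos <- matrix(0, nb, 3L)
  nbr <- max(depths$branch)
  for (b in seq_len(nb)) {
    rad <- R + direction * depths$depth[b] * bond_len
    off <- c(0, 0)
    if (depths$branch[b] > 0L && nbr > 0L) {
      ang <- 2 * pi * (depths$branch[b] - 1L) / max(1L, nbr)
      off <- 0.25 * c(cos(ang), sin(ang))
    }
    pos[b, ] <- center + rad * u + off[1] * t1 + off[2] * t2
  }
  pos
}

#' Build a preformed spherical bilayer vesicle
#'
#' Places lipids on two concentric leaflets: outer-leaflet heads on the
#' sphere of radius `vesicle_radius`, inner-leaflet heads at
#' `vesicle_radius - bilayer_thickness`, tails pointing toward the bilayer
#' mid-surface. The lipid count per leaflet is `round(4 pi R^2 /
#' area_per_lipid)` on the respective head sphere; head positions follow a
#' deterministic Fibonacci (low-discrepancy) lattice, so the construction
#' depends only on the configuration.
#'
#' @param config A [build_config()].
#' @param topology Lipid topology (default [lecithin_topology()]).
#' @param bond_len Initial bond spacing along the lipid (rc).
#' @return A molecule-set list (positions, species, molecule ids, bonds)
#'   centered at the box center.
#' @export
build_vesicle <- function(config, topology = lecithin_topology(),
                          bond_len = 0.7) {
  stopifnot(inherits(config, "build_config"))
  R_out <- config$vesicle_radius
  R_in <- R_out - config$bilayer_thickness
  center <- config$box$lengths / 2
  depths <- topology_depths(topology)
  ms <- empty_molecule_set()
  for (leaf in list(list(R = R_out, dir = -1), list(R = R_in, dir = +1))) {
    n_lip <- round(4 * pi * leaf$R^2 / config$area_per_lipid)
    if (n_lip < 1L) next
    us <- fibonacci_sphere(n_lip)
    for (k in seq_len(n_lip)) {
      pos <- place_lipid(topology, center, us[k, ], leaf$R, leaf$dir,
                         bond_len, depths)
      ms <- add_molecule(ms, pos, topology)
    }
  }
  ms
}

# one random unit vector from the current RNG stream
runit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

#' Scatter solute molecules outside the vesicle
#'
#' Places each capsaicin molecule and chitosan chain at a random position
#' and orientation in the solvent region outside `vesicle_radius + 1` rc
#' from the box center, growing each bonded chain as a random walk with
#' step `bond_len` whose beads must stay outside the vesicle radius.
#' Reproducible through R's RNG stream.
#'
#' @param config A [build_config()].
#' @param capsaicin,chitosan Topologies for the two solute species.
#' @param bond_len Bond step length (rc).
#' @param max_tries Placement retries per molecule before failing.
#' @return A molecule-set list.
#' @export
scatter_solutes <- function(config, capsaicin = capsaicin_topology(),
                            chitosan = chitosan_topology(config$sequence),
                            bond_len = 0.7, max_tries = 200L) {
  stopifnot(inherits(config, "build_config"))
  center <- config$box$lengths / 2
  L <- config$box$lengths
  R_excl <- config$vesicle_radius        # no bead may enter the vesicle
  R_start <- config$vesicle_radius + 1   # first bead clearance
  if (R_start >= min(L) / 2 &&
      (config$n_capsaicin > 0L || config$n_chitosan > 0L)) {
    # still allowed: box corners extend beyond min(L)/2
    corner <- sqrt(sum((L / 2)^2))
    if (R_start >= corner) {
      stop("no exterior volume outside the vesicle", call. = FALSE)
    }
  }
  grow_molecule <- function(topo) {
    for (try in seq_len(max_tries)) {
      p0 <- stats::runif(3) * L
      if (sqrt(sum((p0 - center)^2)) <= R_start) next
      nb <- length(topo$beads)
      pos <- matrix(0, nb, 3L)
      pos[1L, ] <- p0
      ok <- TRUE
      for (b in seq_len(nb)[-1L]) {
        placed <- FALSE
        for (sub in 1:50) {
          cand <- pos[b - 1L, ] + bond_len * runit()
          # minimum-image distance from the vesicle center
          d <- cand - center
          d <- d - round(d / L) * L
          if (sqrt(sum(d^2)) > R_excl) {
            pos[b, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(pos)
    }
    stop("insufficient exterior volume to place solutes after ",
         max_tries, " retries", call. = FALSE)
  }
  ms <- empty_molecule_set()
  for (k in seq_len(config$n_capsaicin)) {
    ms <- add_molecule(ms, grow_molecule(capsaicin), capsaicin)
  }
  for (k in seq_len(config$n_chitosan)) {
    ms <- add_molecule(ms, grow_molecule(chitosan), chitosan)
  }
  ms
}

#' Fill a system with solvent beads to a target density
#'
#' Inserts water (`W`) beads uniformly at random so that the total bead
#' count equals `round(target_density * V_box)`. Soft DPD potentials allow
#' overlaps, so no exclusion test is performed; a short capped-force
#' pre-equilibration relaxes any close contacts.
#'
#' @param ms A molecule-set list (may be empty).
#' @param box A `box_spec`.
#' @param target_density Beads per rc^3.
#' @return The molecule set with solvent appended.
#' @export
fill_solvent <- function(ms, box, target_density = 3) {
  stopifnot(inherits(box, "box_spec"))
  if (target_density <= 0) stop("density must be positive", call. = FALSE)
  n_target <- round(target_density * prod(box$lengths))
  n_now <- nrow(ms$positions)
  n_w <- n_target - n_now
  if (n_w < 0) {
    stop("target density already exceeded (", n_now, " beads, target ",
         n_target, ")", call. = FALSE)
  }
  if (n_w == 0L) return(ms)
  wpos <- matrix(stats::runif(3 * n_w), n_w, 3L) %*% diag(box$lengths)
  wt <- water_topology()
  offset <- nrow(ms$positions)
  mol_offset <- length(ms$molecule_species)
  ms$positions <- rbind(ms$positions, wpos)
  ms$species <- c(ms$species, rep("W", n_w))
  ms$molecule_id <- c(ms$molecule_id, mol_offset + seq_len(n_w))
  ms$molecule_species <- c(ms$molecule_species, rep(wt$species, n_w))
  ms
}

#' Build the full initial configuration
#'
#' Composes [build_vesicle()], [scatter_solutes()] and [fill_solvent()]
#' into a `simulation_state`: a preformed lecithin vesicle at the box
#' center, capsaicin and chitosan scattered randomly outside it, and
#' solvent filled to the target density. Deterministic given
#' `config$rng_seed`.
#'
#' @param config A [build_config()].
#' @param lipid Lipid topology.
#' @param capsaicin Capsaicin topology.
#' @param bond_len Initial bond spacing (rc).
#' @return A `simulation_state` with zero velocities.
#' @export
#' @examples
#' cfg <- build_config(vesicle_radius = 5, bilayer_thickness = 2.5,
#'                     n_capsaicin = 5, n_chitosan = 1,
#'                     box = box_spec(14), rng_seed = 7)
#' st <- build_system(cfg)
#' number_density(st)  # 3 (within one-bead rounding)
build_system <- function(config, lipid = lecithin_topology(),
                         capsaicin = capsaicin_topology(), bond_len = 0.7) {
  stopifnot(inherits(config, "build_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)
  ms <- build_vesicle(config, lipid, bond_len)
  sol <- scatter_solutes(config, capsaicin,
                         chitosan_topology(config$sequence), bond_len)
  ms <- merge_molecule_sets(ms, sol)
  ms <- fill_solvent(ms, config$box, config$target_density)
  simulation_state(
    positions = ms$positions, box = config$box$lengths,
    species = ms$species, molecule_id = ms$molecule_id,
    molecule_species = ms$molecule_species, bonds = ms$bonds)
}
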