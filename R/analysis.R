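# Observable estimators: planar density maps, radial profiles, COM pair
# correlations and potentials of mean force, vesicle size, encapsulation
# efficiency. All estimators work on dpd_trajectory objects (or single
# simulation_state frames) in reduced units.

min_image_vec <- function(d, L) d - round(d / L) * L

# circular-mean center of a set of wrapped coordinates (robust to the
# cluster straddling a periodic boundary)
periodic_center <- function(pos, L) {
  vapply(1:3, function(d) {
    th <- 2 * pi * pos[, d] / L[d]
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) / (2 * pi) * L[d]
  }, numeric(1))
}

as_frame_list <- function(x) {
  if (inherits(x, "dpd_trajectory")) {
    list(frames = lapply(x$frames, `[[`, "positions"), box = x$box,
         species = x$species, molecule_id = x$molecule_id,
         molecule_species = x$molecule_species)
  } else if (inherits(x, "simulation_state")) {
    list(frames = list(x$positions), box = x$box, species = x$species,
         molecule_id = x$molecule_id, molecule_species = x$molecule_species)
  } else {
    stop("expected a dpd_trajectory or simulation_state", call. = FALSE)
  }
}

#' Vesicle center of a frame
#'
#' The center of the lecithin bead cloud, computed by a periodic (circular)
#' mean in each coordinate so a vesicle straddling the box boundary is
#' handled correctly.
#'
#' @param positions N x 3 wrapped coordinates.
#' @param species Bead labels (length N).
#' @param box Box edge lengths.
#' @param lipid_beads Bead types defining the vesicle (default the lecithin
#'   types).
#' @return Length-3 center position.
#' @export
vesicle_center <- function(positions, species, box,
                           lipid_beads = c("L1", "L2", "L3")) {
  sel <- species %in% lipid_beads
  if (!any(sel)) stop("no lipid beads to define the vesicle center",
                      call. = FALSE)
  periodic_center(positions[sel, , drop = FALSE], box)
}

#' Molecular centers of mass
#'
#' Equal-mass bead average per molecule. Each molecule is unwrapped before
#' averaging by chaining minimum-image displacements between consecutive
#' beads (bonded neighbours are always much closer than half the box), so a
#' molecule straddling the periodic boundary gets the correct center, which
#' is then wrapped back into the box.
#'
#' @param x A `dpd_trajectory` frame index is not needed; pass a
#'   `simulation_state` or a list with positions/species/molecule info.
#' @param species Molecule species name (e.g. `"capsaicin"`), or `NULL` for
#'   all molecules.
#' @return A matrix of COM positions (one row per molecule) with the
#'   molecule ids as rownames.
#' @export
molecule_com <- function(x, species = NULL) {
  fl <- as_frame_list(x)
  pos <- fl$frames[[1]]
  molecule_com_impl(pos, fl$molecule_id, fl$molecule_species, fl$box, species)
}

molecule_com_impl <- function(pos, molecule_id, molecule_species, box,
                              species = NULL) {
  keep_mol <- if (is.null(species)) {
    unique(molecule_id)
  } else {
    which(molecule_species %in% species)
  }
  if (length(keep_mol) == 0L) {
    stop("species absent from frame: ", paste(species, collapse = ", "),
         call. = FALSE)
  }
  sel <- molecule_id %in% keep_mol
  p <- pos[sel, , drop = FALSE]
  mid <- molecule_id[sel]
  ord <- order(mid)
  p <- p[ord, , drop = FALSE]
  mid <- mid[ord]
  # sequential minimum-image unwrap within each molecule
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  for (k in 1:3) d[, k] <- min_image_vec(d[, k], box[k])
  new_mol <- c(TRUE, mid[-1L] != mid[-length(mid)])
  d[new_mol[-1L], ] <- 0
  steps <- rbind(c(0, 0, 0), d)
  # reset cumulative sum at each molecule start: add back the absolute pos
  anchor <- apply(steps, 2, cumsum)
  if (!is.matrix(anchor)) anchor <- matrix(anchor, nrow = 1L)
  first_rows <- which(new_mol)
  base <- p[first_rows, , drop = FALSE] - anchor[first_rows, , drop = FALSE]
  unwrapped <- anchor + base[rep(seq_along(first_rows),
                                 times = diff(c(first_rows, length(mid) + 1L))),
                             , drop = FALSE]
  com <- rowsum(unwrapped, group = mid) / as.vector(table(mid))
  for (k in 1:3) com[, k] <- com[, k] %% box[k]
  com
}

# ---------------------------------------------------------------------------
# Density maps and radial profiles
# ---------------------------------------------------------------------------

#' Time-averaged xy-plane density map
#'
#' Bead number density of one species projected on the xy plane, restricted
#' to a z-slab of thickness `slab_thickness` centered on the vesicle center
#' (or the box center if no lipids are present), averaged over frames. Bins
#' are `bin_width` x `bin_width`, coordinates are offsets from the slab
#' center. The integral of the map times the bin area and slab thickness
#' recovers the mean in-slab bead count.
#'
#' @param traj A `dpd_trajectory` (or single `simulation_state`).
#' @param species Bead types to map (e.g. `c("L1","L2","L3")`) or a
#'   molecule species name such as `"lecithin"`.
#' @param bin_width Bin edge (rc), default 0.5.
#' @param slab_thickness z-extent of the slab (rc), default 2; `Inf`
#'   projects the full box.
#' @return A `density_map` object: list with `grid` (x by y matrix of
#'   densities, beads per rc^3), bin centers `x`, `y`, and metadata.
#' @export
density_map_xy <- function(traj, species, bin_width = 0.5,
                           slab_thickness = 2) {
  fl <- as_frame_list(traj)
  if (slab_thickness <= 0) stop("empty slab", call. = FALSE)
  sel <- bead_selection(fl, species)
  L <- fl$box
  half <- min(L[1], L[2]) / 2
  edges <- seq(-half, half, by = bin_width)
  nb <- length(edges) - 1L
  grid <- matrix(0, nb, nb)
  slab <- min(slab_thickness, L[3])
  for (pos in fl$frames) {
    ctr <- tryCatch(vesicle_center(pos, fl$species, L),
                    error = function(e) L / 2)
    dx <- min_image_vec(pos[sel, 1L] - ctr[1L], L[1])
    dy <- min_image_vec(pos[sel, 2L] - ctr[2L], L[2])
    dz <- min_image_vec(pos[sel, 3L] - ctr[3L], L[3])
    inslab <- abs(dz) <= slab / 2
    ix <- findInterval(dx[inslab], edges, rightmost.closed = TRUE)
    iy <- findInterval(dy[inslab], edges, rightmost.closed = TRUE)
    ok <- ix >= 1L & ix <= nb & iy >= 1L & iy <= nb
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(nb)),
                   factor(iy[ok], levels = seq_len(nb)))
      grid <- grid + unclass(tab)
    }
  }
  grid <- grid / (bin_width^2 * slab * length(fl$frames))
  structure(list(
    grid = grid,
    x = (edges[-1L] + edges[-length(edges)]) / 2,
    y = (edges[-1L] + edges[-length(edges)]) / 2,
    bin_width = bin_width, slab_thickness = slab,
    species = species, n_frames = length(fl$frames)
  ), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %s: %d x %d bins of %.3g rc, slab %.3g rc, %d frame(s), max %.3g beads/rc^3\n",
    paste(x$species, collapse = "+"), nrow(x$grid), ncol(x$grid),
    x$bin_width, x$slab_thickness, x$n_frames, max(x$grid)))
  invisible(x)
}

bead_selection <- function(fl, species) {
  if (all(species %in% bead_types())) {
    fl$species %in% species
  } else if (!is.null(fl$molecule_species)) {
    fl$molecule_id %in% which(fl$molecule_species %in% species)
  } else {
    stop("unknown species selection: ", paste(species, collapse = ", "),
         call. = FALSE)
  }
}

#' Spherically averaged radial density profile
#'
#' Number density of one species in spherical shells around the vesicle
#' center (recomputed per frame from the lecithin beads), averaged over
#' frames. Shells are normalized by their exact volume, so the volume
#' integral of the profile recovers the species bead count.
#'
#' @inheritParams density_map_xy
#' @param dr Shell width (rc), default 0.25.
#' @param center Fixed center (length-3), or `NULL` to use the per-frame
#'   lecithin center.
#' @return A `radial_profile` data.frame with columns `r` (bin centers) and
#'   `density` (beads per rc^3), with metadata attributes.
#' @export
radial_density_profile <- function(traj, species, dr = 0.25, center = NULL) {
  fl <- as_frame_list(traj)
  sel <- bead_selection(fl, species)
  L <- fl$box
  rmax <- min(L) / 2
  edges <- seq(0, rmax, by = dr)
  counts <- numeric(length(edges) - 1L)
  for (pos in fl$frames) {
    ctr <- if (is.null(center)) vesicle_center(pos, fl$species, L) else center
    d <- sweep(pos[sel, , drop = FALSE], 2L, ctr)
    for (k in 1:3) d[, k] <- min_image_vec(d[, k], L[k])
    r <- sqrt(rowSums(d^2))
    h <- findInterval(r, edges, rightmost.closed = TRUE)
    ok <- h >= 1L & h <= length(counts)
    counts <- counts + tabulate(h[ok], nbins = length(counts))
  }
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  dens <- counts / (shell_vol * length(fl$frames))
  out <- data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2,
                    density = dens)
  attr(out, "dr") <- dr
  attr(out, "species") <- species
  attr(out, "n_frames") <- length(fl$frames)
  class(out) <- c("radial_profile", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# COM pair correlations and PMF
# ---------------------------------------------------------------------------

#' Radial distribution function of molecular centers of mass
#'
#' Histogram of minimum-image COM separations between two molecular
#' species, normalized by the ideal-gas expectation, averaged over frames.
#' Valid only up to half the smallest box edge. For `species_a ==
#' species_b`, self-pairs are excluded and each unordered pair counted
#' once.
#'
#' @param traj A `dpd_trajectory` (or `simulation_state`).
#' @param species_a,species_b Molecule species names (e.g. `"lecithin"`,
#'   `"chitosan"`).
#' @param dr Bin width (rc), default 0.1.
#' @return A `pair_gr` data.frame with columns `r`, `g`, and `count`.
#' @export
pair_gr <- function(traj, species_a, species_b, dr = 0.1) {
  fl <- as_frame_list(traj)
  L <- fl$box
  V <- prod(L)
  rmax <- min(L) / 2
  edges <- seq(0, rmax, by = dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  npairs_ideal <- 0
  same <- identical(species_a, species_b)
  for (pos in fl$frames) {
    ca <- molecule_com_impl(pos, fl$molecule_id, fl$molecule_species, L,
                            species_a)
    cb <- if (same) ca else {
      molecule_com_impl(pos, fl$molecule_id, fl$molecule_species, L,
                        species_b)
    }
    na <- nrow(ca)
    nb_mol <- nrow(cb)
    if (na + nb_mol < 2L) stop("fewer than 2 molecules", call. = FALSE)
    dists <- com_pair_distances(ca, cb, L, same)
    h <- findInterval(dists, edges, rightmost.closed = TRUE)
    ok <- h >= 1L & h <= nb
    counts <- counts + tabulate(h[ok], nbins = nb)
    npairs_ideal <- npairs_ideal +
      if (same) na * (na - 1) / 2 else na * nb_mol
  }
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  expected <- npairs_ideal * shell_vol / V
  g <- ifelse(expected > 0, counts / expected, 0)
  out <- data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2,
                    g = g, count = counts)
  attr(out, "species") <- c(species_a, species_b)
  attr(out, "n_frames") <- length(fl$frames)
  class(out) <- c("pair_gr", "data.frame")
  out
}

com_pair_distances <- function(ca, cb, L, same) {
  if (same) {
    n <- nrow(ca)
    if (n < 2L) return(numeric(0))
    out <- numeric(n * (n - 1) / 2)
    idx <- 1L
    for (i in seq_len(n - 1L)) {
      d <- sweep(ca[(i + 1L):n, , drop = FALSE], 2L, ca[i, ])
      for (k in 1:3) d[, k] <- min_image_vec(d[, k], L[k])
      m <- nrow(d)
      out[idx:(idx + m - 1L)] <- sqrt(rowSums(d^2))
      idx <- idx + m
    }
    out
  } else {
    unlist(lapply(seq_len(nrow(ca)), function(i) {
      d <- sweep(cb, 2L, ca[i, ])
      for (k in 1:3) d[, k] <- min_image_vec(d[, k], L[k])
      sqrt(rowSums(d^2))
    }))
  }
}

#' Potential of mean force from a radial distribution function
#'
#' `w(r) = -kT ln g(r)`, anchored so the mean over the outermost 10% of
#' sampled bins is zero (the PMF vanishes at large separation). Bins with
#' `g = 0` are undefined (`NA`).
#'
#' @param gr A `pair_gr` data.frame (or any data.frame with `r`, `g`).
#' @param kT Reduced temperature (default 1).
#' @return A `pmf_curve` data.frame with columns `r` and `w` (kT).
#' @export
pmf_from_gr <- function(gr, kT = 1) {
  g <- gr$g
  if (all(g <= 0)) stop("all-zero g(r): PMF undefined", call. = FALSE)
  w <- ifelse(g > 0, -kT * log(g), NA_real_)
  n_tail <- max(1L, ceiling(0.1 * length(w)))
  tail_idx <- utils::tail(seq_along(w), n_tail)
  shift <- mean(w[tail_idx], na.rm = TRUE)
  if (is.nan(shift)) {
    # fall back to the outermost defined bins
    def <- which(!is.na(w))
    shift <- mean(w[utils::tail(def, n_tail)])
  }
  out <- data.frame(r = gr$r, w = w - shift)
  attr(out, "species") <- attr(gr, "species")
  attr(out, "kT") <- kT
  class(out) <- c("pmf_curve", "data.frame")
  out
}

#' Depth of the attractive well of a PMF curve
#'
#' The minimum of `w(r)` over the sampled range (NA bins ignored);
#' negative for a net attraction.
#'
#' @param pmf A `pmf_curve`.
#' @param r_max Consider only `r <= r_max` (default all).
#' @return Well depth in kT.
#' @export
pmf_well_depth <- function(pmf, r_max = Inf) {
  sel <- pmf$r <= r_max & !is.na(pmf$w)
  if (!any(sel)) stop("no defined PMF bins in range", call. = FALSE)
  min(pmf$w[sel])
}

# ---------------------------------------------------------------------------
# Vesicle size and encapsulation efficiency
# ---------------------------------------------------------------------------

#' Outermost half-maximum radius of a radial profile
#'
#' The largest radius at which the density falls to half of its peak,
#' located by linear interpolation between the bracketing bins. Requires a
#' clear membrane peak: the maximum must exceed twice the far-field density
#' (mean over the outermost 10% of bins).
#'
#' @param profile A `radial_profile`.
#' @return Radius in rc.
#' @export
half_max_outer_radius <- function(profile) {
  rho <- profile$density
  r <- profile$r
  peak <- max(rho)
  n_tail <- max(1L, ceiling(0.1 * length(rho)))
  far <- mean(utils::tail(rho, n_tail))
  if (!(peak > 2 * far) || peak <= 0) {
    stop("no membrane peak in radial profile", call. = FALSE)
  }
  half <- peak / 2
  ipk <- which.max(rho)
  above <- which(rho >= half)
  iout <- max(above)
  if (iout == length(rho)) return(r[iout])
  # linear interpolation between the last bin above half-max and the next
  r1 <- r[iout]; r2 <- r[iout + 1L]
  d1 <- rho[iout]; d2 <- rho[iout + 1L]
  r1 + (d1 - half) / (d1 - d2) * (r2 - r1)
}

#' Mean vesicle diameter from the lecithin radial profile
#'
#' Diameter = twice the outermost half-maximum radius of the lecithin
#' density profile. Given a trajectory, the profile is computed per block
#' of frames and the block spread is reported as the uncertainty; given a
#' single profile, a point estimate is returned.
#'
#' @param x A `radial_profile` of the lipid species, or a
#'   `dpd_trajectory`.
#' @param length_scale nm per rc for the physical diameter.
#' @param species Bead types defining the membrane (used for trajectories).
#' @param dr Shell width for trajectory profiles.
#' @param n_blocks Number of frame blocks for the uncertainty estimate.
#' @return A list with `diameter_rc`, `diameter_nm`, and (for
#'   trajectories) `sd_rc`, `sd_nm` over blocks.
#' @export
mean_diameter <- function(x, length_scale = 0.646,
                          species = c("L1", "L2", "L3"), dr = 0.25,
                          n_blocks = 5L) {
  if (inherits(x, "radial_profile")) {
    d_rc <- 2 * half_max_outer_radius(x)
    return(list(diameter_rc = d_rc, diameter_nm = d_rc * length_scale,
                sd_rc = NA_real_, sd_nm = NA_real_))
  }
  stopifnot(inherits(x, "dpd_trajectory"))
  nf <- n_frames(x)
  n_blocks <- max(1L, min(n_blocks, nf))
  blocks <- split(seq_len(nf), cut(seq_len(nf), n_blocks, labels = FALSE))
  d_blocks <- vapply(blocks, function(idx) {
    sub <- x
    sub$frames <- x$frames[idx]
    prof <- radial_density_profile(sub, species, dr = dr)
    2 * half_max_outer_radius(prof)
  }, numeric(1))
  d_rc <- mean(d_blocks)
  sd_rc <- if (length(d_blocks) > 1L) stats::sd(d_blocks) else NA_real_
  list(diameter_rc = d_rc, diameter_nm = d_rc * length_scale,
       sd_rc = sd_rc, sd_nm = sd_rc * length_scale)
}

#' Encapsulation efficiency
#'
#' `EE = ((CapsT - CapsF) / CapsT) * 100`: the percentage of drug
#' molecules associated with the carrier, where `CapsT` is the total drug
#' count and `CapsF` the count free in solution.
#'
#' @param caps_total Total number of drug molecules (> 0).
#' @param caps_free Number free in solution (0 <= caps_free <= caps_total).
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' encapsulation_efficiency(250, 8)  # 96.8
encapsulation_efficiency <- function(caps_total, caps_free) {
  if (caps_total <= 0) stop("caps_total must be positive", call. = FALSE)
  if (caps_free < 0 || caps_free > caps_total) {
    stop("caps_free must lie in [0, caps_total]", call. = FALSE)
  }
  (caps_total - caps_free) / caps_total * 100
}

#' Mean count of free capsaicin molecules
#'
#' Counts capsaicin molecules whose COM lies farther from the vesicle
#' center than `boundary_radius`, averaged over frames. The default
#' boundary is the outer half-maximum radius of the lecithin profile plus
#' 1 rc, tying the free/bound classifier to the measured membrane edge.
#'
#' @param traj A `dpd_trajectory`.
#' @param boundary_radius Radius (rc) separating bound from free; `NULL`
#'   for the default rule.
#' @param species Molecule species of the drug (default `"capsaicin"`).
#' @return A list with `mean_free` (per-frame average), `boundary_radius`,
#'   and `per_frame` counts.
#' @export
count_free_capsaicin <- function(traj, boundary_radius = NULL,
                                 species = "capsaicin") {
  fl <- as_frame_list(traj)
  L <- fl$box
  if (is.null(boundary_radius)) {
    prof <- radial_density_profile(traj, c("L1", "L2", "L3"))
    boundary_radius <- half_max_outer_radius(prof) + 1
  }
  if (boundary_radius <= 0 || boundary_radius > min(L) / 2) {
    stop("boundary_radius must lie in (0, L/2]", call. = FALSE)
  }
  per_frame <- vapply(fl$frames, function(pos) {
    ctr <- vesicle_center(pos, fl$species, L)
    com <- molecule_com_impl(pos, fl$molecule_id, fl$molecule_species, L,
                             species)
    d <- sweep(com, 2L, ctr)
    for (k in 1:3) d[, k] <- min_image_vec(d[, k], L[k])
    sum(sqrt(rowSums(d^2)) > boundary_radius)
  }, numeric(1))
  list(mean_free = mean(per_frame), boundary_radius = boundary_radius,
       per_frame = per_frame)
}
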