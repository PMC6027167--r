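test_that("molecule COM averages unwrapped bead positions", {
  # linear 3-bead molecule
  st <- simulation_state(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rep(10, 3), c("C1", "C2", "C3"), rep(1L, 3),
                         molecule_species = "capsaicin")
  expect_equal(unname(molecule_com(st, "capsaicin")[1, ]), c(1, 0, 0))

  # molecule straddling the boundary: beads at x = 9.5 and 0.5 in L = 10
  st2 <- simulation_state(rbind(c(9.5, 2, 2), c(0.5, 2, 2)),
                          rep(10, 3), c("G", "A"), rep(1L, 2),
                          molecule_species = "chitosan")
  expect_equal(unname(molecule_com(st2, "chitosan")[1, ]), c(0, 2, 2))

  # single-bead molecule is its own COM
  st3 <- simulation_state(matrix(c(3, 4, 5), 1, 3), rep(10, 3), "W", 1L,
                          molecule_species = "water")
  expect_equal(unname(molecule_com(st3, "water")[1, ]), c(3, 4, 5))

  expect_error(molecule_com(st3, "capsaicin"), "absent")
})

test_that("xy density maps are normalized bead densities", {
  st <- solvent_fluid(10, seed = 12)
  # uniform fluid, full-box slab: every bin near the global density
  m <- density_map_xy(st, "W", bin_width = 2.5, slab_thickness = Inf)
  expect_true(all(abs(m$grid - 3) < 0.5))
  # integral identity: sum * bin_area * slab = in-slab count
  m2 <- density_map_xy(st, "W", bin_width = 0.5, slab_thickness = 2)
  count_in_slab <- sum(abs(st$positions[, 3] - 5) <= 1)
  expect_equal(sum(m2$grid) * 0.25 * 2, count_in_slab, tolerance = 0.01)
  # absent species: all-zero map
  m3 <- density_map_xy(st, "C1", bin_width = 2.5, slab_thickness = Inf)
  expect_true(all(m3$grid == 0))
  expect_error(density_map_xy(st, "W", slab_thickness = 0), "slab")
})

test_that("radial profiles integrate back to bead counts", {
  st <- solvent_fluid(10, seed = 13)
  prof <- radial_density_profile(st, "W", dr = 0.5, center = rep(5, 3))
  # flat at the fluid density away from r = 0 (tiny shells are noisy)
  expect_equal(mean(prof$density[prof$r > 1.5]), 3, tolerance = 0.05)
  # volume integral recovers the in-sphere count within 1%
  shell_counts <- prof$density * 4 / 3 * pi *
    ((prof$r + 0.25)^3 - (prof$r - 0.25)^3)
  d <- sweep(st$positions, 2, rep(5, 3))
  in_sphere <- sum(rowSums(d^2) < 5^2)
  expect_equal(sum(shell_counts), in_sphere, tolerance = 0.01)

  # synthetic delta shell peaks in the right bin
  sh <- delta_shell_state(R = 6, n = 800, L = 24)
  p2 <- radial_density_profile(sh, "L1", dr = 0.5)
  expect_equal(p2$r[which.max(p2$density)], 6.25, tolerance = 0.26)
  # all mass in the one or two bins bracketing the shell radius
  expect_lte(sum(p2$density > 0), 2)
  expect_true(all(which(p2$density > 0) %in% c(12, 13)))

  expect_error(radial_density_profile(st, "W"), "lipid")
})

test_that("COM g(r) matches a brute-force histogram and is ~1 for ideal gas", {
  # ideal-gas: two species of single-bead molecules, uniform positions
  set.seed(21)
  L <- 12
  na <- 300
  nb <- 300
  pos <- matrix(runif((na + nb) * 3) * L, na + nb, 3)
  st <- simulation_state(pos, rep(L, 3),
                         c(rep("C1", na), rep("G", nb)),
                         seq_len(na + nb),
                         molecule_species = c(rep("capsaicin", na),
                                              rep("chitosan", nb)))
  gr <- pair_gr(st, "capsaicin", "chitosan", dr = 0.5)
  expect_equal(mean(gr$g[gr$r > 1]), 1, tolerance = 0.05)
  # bins stop at L/2
  expect_lte(max(gr$r), L / 2)

  # exact count comparison against a brute-force distance histogram
  sub <- simulation_state(pos[1:20, ], rep(L, 3), rep("C1", 20), 1:20,
                          molecule_species = rep("capsaicin", 20))
  gr2 <- pair_gr(sub, "capsaicin", "capsaicin", dr = 0.25)
  d <- numeric(0)
  for (i in 1:19) for (j in (i + 1):20) {
    dv <- pos[i, ] - pos[j, ]
    dv <- dv - round(dv / L) * L
    d <- c(d, sqrt(sum(dv^2)))
  }
  edges <- seq(0, L / 2, by = 0.25)
  h <- hist(d[d < L / 2], breaks = edges, plot = FALSE)$counts
  expect_equal(gr2$count, h)
})

test_that("PMF transform obeys its identities", {
  gr <- data.frame(r = seq(0.05, 5, by = 0.1), g = 1)
  w <- pmf_from_gr(gr)
  expect_true(all(abs(w$w) < 1e-12))

  # synthetic w round-trips through g = exp(-w) up to the tail anchor
  r <- seq(0.05, 5, by = 0.05)
  w_true <- -1.2 * exp(-(r - 1.5)^2 / 0.3) + 0.4 * exp(-(r - 2.5)^2 / 0.2)
  gr2 <- data.frame(r = r, g = exp(-w_true))
  w_est <- pmf_from_gr(gr2)
  shift <- mean(w_true[utils::tail(seq_along(r), ceiling(0.1 * length(r)))])
  expect_equal(w_est$w, w_true - shift, tolerance = 1e-10)

  # g(r0) = 1/e with unit tail gives +1 kT
  g3 <- c(rep(1, 40), exp(-1), rep(1, 40))
  w3 <- pmf_from_gr(data.frame(r = seq_along(g3) * 0.1, g = g3))
  expect_equal(w3$w[41], 1)

  # order reversal: higher g peak means deeper well
  expect_lt(pmf_from_gr(data.frame(r = r, g = 1 + exp(-(r - 2)^2)))$w[40],
            pmf_from_gr(data.frame(r = r, g = 1 + 0.5 * exp(-(r - 2)^2)))$w[40])

  # zero bins are undefined, all-zero errors
  gz <- data.frame(r = 1:10, g = c(0, rep(1, 9)))
  expect_true(is.na(pmf_from_gr(gz)$w[1]))
  expect_error(pmf_from_gr(data.frame(r = 1:5, g = rep(0, 5))), "all-zero")
})

test_that("encapsulation efficiency is the printed percentage", {
  expect_equal(encapsulation_efficiency(250, 8), 96.8)
  expect_equal(encapsulation_efficiency(100, 100), 0)
  expect_equal(encapsulation_efficiency(100, 0), 100)
  # scale-free: doubling both counts leaves EE unchanged
  expect_equal(encapsulation_efficiency(500, 16),
               encapsulation_efficiency(250, 8))
  expect_error(encapsulation_efficiency(0, 0), "positive")
  expect_error(encapsulation_efficiency(10, 11), "caps_free")
  expect_error(encapsulation_efficiency(10, -1), "caps_free")
})

test_that("free-capsaicin counting respects the boundary rule", {
  # vesicle shell of lecithin heads at R = 5 plus capsaicin molecules:
  # 3 bound inside the boundary, 2 free outside
  L <- 24
  shell <- delta_shell_state(R = 5, n = 400, L = L)
  caps_r <- c(1, 3, 4, 9, 10)
  caps_pos <- do.call(rbind, lapply(caps_r, function(r) {
    ctr <- rep(L / 2, 3)
    rbind(ctr + c(r, 0, 0), ctr + c(r, 0.7, 0), ctr + c(r, 1.4, 0))
  }))
  pos <- rbind(shell$positions, caps_pos)
  st <- simulation_state(
    pos, rep(L, 3),
    c(shell$species, rep(c("C1", "C2", "C3"), 5)),
    c(shell$molecule_id, rep(401:405, each = 3)),
    molecule_species = c(shell$molecule_species, rep("capsaicin", 5)))

  free <- count_free_capsaicin(st, boundary_radius = 6)
  expect_equal(free$mean_free, 2)
  # monotonically non-increasing in the boundary radius
  free2 <- count_free_capsaicin(st, boundary_radius = 9.5)
  expect_lte(free2$mean_free, free$mean_free)
  # all inside a huge boundary: none free
  expect_equal(count_free_capsaicin(st, boundary_radius = 11)$mean_free, 0)
  expect_error(count_free_capsaicin(st, boundary_radius = 13), "L/2")
})

test_that("vesicle diameter comes from the outer half-maximum crossing", {
  # constructed profile: peak 4 at r = 13, falls to exactly half at r = 14
  r <- seq(0.5, 20, by = 1)
  rho <- rep(0, length(r))
  rho[r == 12.5] <- 3
  rho[r == 13.5] <- 4
  rho[r == 14.5] <- 2  # == half max, outermost bin above half
  prof <- structure(data.frame(r = r - 0.0, density = rho),
                    class = c("radial_profile", "data.frame"))
  d <- mean_diameter(prof, length_scale = 0.646)
  expect_equal(d$diameter_rc, 2 * 14.5)
  expect_equal(d$diameter_nm, 2 * 14.5 * 0.646)
  # doubling the length scale doubles nm, leaves rc unchanged
  d2 <- mean_diameter(prof, length_scale = 1.292)
  expect_equal(d2$diameter_nm, 2 * d$diameter_nm)
  expect_equal(d2$diameter_rc, d$diameter_rc)

  # interpolated crossing: density 4 at 13.5 dropping to 0 at 14.5
  rho2 <- rep(0, length(r))
  rho2[r == 13.5] <- 4
  prof2 <- structure(data.frame(r = r, density = rho2),
                     class = c("radial_profile", "data.frame"))
  # half-max 2 crossed halfway between 13.5 and 14.5
  expect_equal(mean_diameter(prof2)$diameter_rc, 2 * 14)

  # structureless profile has no membrane peak
  flat <- structure(data.frame(r = r, density = rep(3, length(r))),
                    class = c("radial_profile", "data.frame"))
  expect_error(mean_diameter(flat), "no membrane peak")
})
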