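test_that("fluctuation-dissipation ties sigma to gamma", {
  p <- dpd_params(gamma = 4.5, kT = 1)
  expect_equal(p$sigma, 3)
  expect_equal(p$sigma^2, 2 * p$gamma * p$kT)
  expect_silent(dpd_params(gamma = 4.5, kT = 1, sigma = 3))
  expect_error(dpd_params(gamma = 4.5, kT = 1, sigma = 2.5),
               "fluctuation-dissipation")
  p2 <- dpd_params(gamma = 2, kT = 0.5)
  expect_equal(p2$sigma^2, 2 * 2 * 0.5)
})

test_that("conservative pair force is the linear soft repulsion", {
  f <- conservative_pair_force(25, c(0.5, 0, 0))
  expect_equal(f, c(12.5, 0, 0))
  expect_equal(sqrt(sum(conservative_pair_force(25, c(0.3, 0.4, 0))^2)),
               25 * (1 - 0.5))
  expect_equal(conservative_pair_force(25, c(1, 0, 0)), c(0, 0, 0))
  expect_equal(conservative_pair_force(25, c(2, 1, 3)), c(0, 0, 0))
  expect_equal(conservative_pair_force(25, c(0, 0, 0)), c(0, 0, 0))
})

test_that("dissipative and random forces have the DPD weights", {
  p <- dpd_params()
  r_vec <- c(0.5, 0, 0)
  # perpendicular relative velocity: no dissipative component
  f_perp <- dissipative_random_pair_force(p, r_vec, c(0, 1, 0), noise = 0)
  expect_equal(f_perp, c(0, 0, 0))
  # head-on approach, noise off: F_D = -gamma (1-r)^2 (e.v) e
  f_d <- dissipative_random_pair_force(p, r_vec, c(-2, 0, 0), noise = 0)
  expect_equal(f_d, c(-4.5 * 0.25 * (-2), 0, 0))
  # pure noise: F_R = sigma (1-r) theta / sqrt(dt)
  f_r <- dissipative_random_pair_force(p, r_vec, c(0, 0, 0), noise = 1.5)
  expect_equal(f_r, c(3 * 0.5 * 1.5 / sqrt(p$dt), 0, 0))
  # beyond cutoff both vanish
  expect_equal(dissipative_random_pair_force(p, c(1.2, 0, 0), c(-2, 0, 0), 1),
               c(0, 0, 0))
})

test_that("bond force is a harmonic spring", {
  bp <- bond_params(k_spring = 100, r0 = 0.7)
  expect_equal(bond_force(bp, c(0.7, 0, 0)), c(0, 0, 0))
  f <- bond_force(bp, c(0.8, 0, 0))
  expect_equal(f, c(-10, 0, 0))  # stretched: pulls i toward j
  expect_equal(bond_force(bp, c(-0.8, 0, 0)), -f)  # antisymmetric
  f_comp <- bond_force(bp, c(0.5, 0, 0))
  expect_equal(f_comp, c(20, 0, 0))  # compressed: pushes outward
})

test_that("pair noise is symmetric and reproducible", {
  n1 <- dpdvesicle:::cpp_pair_noise(7, 100, 3, 9)
  expect_identical(dpdvesicle:::cpp_pair_noise(7, 100, 9, 3), n1)
  expect_identical(dpdvesicle:::cpp_pair_noise(7, 100, 3, 9), n1)
  expect_false(dpdvesicle:::cpp_pair_noise(7, 101, 3, 9) == n1)
  expect_false(dpdvesicle:::cpp_pair_noise(8, 100, 3, 9) == n1)
  # unit variance, zero mean (uniform variate scaled by sqrt(3))
  v <- vapply(1:4000, function(s) dpdvesicle:::cpp_pair_noise(1, s, 0, 1),
              numeric(1))
  expect_lt(abs(mean(v)), 0.05)
  expect_equal(var(v), 1, tolerance = 0.1)
  expect_true(all(abs(v) <= sqrt(3)))
})

test_that("neighbor enumeration handles wrap and degenerate cases", {
  expect_equal(nrow(neighbor_pairs(matrix(numeric(0), 0, 3), rep(5, 3))), 0)
  # two beads across the boundary: separation L - 0.5 pairs via min image
  pos <- rbind(c(0.2, 1, 1), c(4.7, 1, 1))
  p <- neighbor_pairs(pos, rep(5, 3))
  expect_equal(p, rbind(c(1L, 2L)), ignore_attr = TRUE)
  # same two beads straight-line apart beyond cutoff: no pair
  pos2 <- rbind(c(1, 1, 1), c(2.5, 1, 1))
  expect_equal(nrow(neighbor_pairs(pos2, rep(5, 3))), 0)
})

test_that("cell list matches the brute-force oracle in small boxes", {
  set.seed(42)
  for (L in c(2.5, 3.5, 6)) {  # below and above the cell-list threshold
    pos <- matrix(runif(150 * 3) * L, 150, 3)
    expect_identical(neighbor_pairs(pos, rep(L, 3)),
                     brute_force_pairs(pos, rep(L, 3)))
  }
})

test_that("a free particle moves ballistically", {
  st <- simulation_state(matrix(c(1, 1, 1), 1, 3), rep(5, 3), "W", 1L)
  st$velocities <- matrix(c(1, 0, 0), 1, 3)
  p <- dpd_params()
  st2 <- integrate_steps(st, default_interaction_matrix(), bond_params(),
                         p, 1, seed = 1)
  expect_equal(st2$positions[1, ], c(1 + p$dt, 1, 1), tolerance = 1e-12)
  st3 <- integrate_steps(st2, default_interaction_matrix(), bond_params(),
                         p, 9, seed = 1)
  expect_equal(st3$positions[1, ], c(1 + 10 * p$dt, 1, 1), tolerance = 1e-12)
})

test_that("compiled core reproduces a pure-R reference integrator", {
  # three bonded + nonbonded beads in a periodic box, two steps
  L <- c(5, 5, 5)
  pos <- rbind(c(1.0, 1.0, 1.0), c(1.6, 1.2, 1.0), c(4.8, 1.0, 1.1))
  vel <- rbind(c(0.3, -0.1, 0.2), c(-0.2, 0.1, 0.0), c(0.1, 0.2, -0.3))
  species <- c("C1", "C2", "W")
  bonds <- rbind(c(1L, 2L))
  p <- dpd_params()
  bp <- bond_params()
  im <- default_interaction_matrix()
  seed <- 31

  min_img <- function(d) d - round(d / L) * L
  ref_forces <- function(x, v, step) {
    f <- matrix(0, 3, 3)
    for (i in 1:2) for (j in (i + 1):3) {
      rv <- min_img(x[i, ] - x[j, ])
      a_ij <- im[species[i], species[j]]
      theta <- dpdvesicle:::cpp_pair_noise(seed, step, i - 1L, j - 1L)
      fij <- conservative_pair_force(a_ij, rv) +
        dissipative_random_pair_force(p, rv, v[i, ] - v[j, ], theta)
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
    rv <- min_img(x[1, ] - x[2, ])
    fb <- bond_force(bp, rv)
    f[1, ] <- f[1, ] + fb
    f[2, ] <- f[2, ] - fb
    f
  }

  x <- pos
  v <- vel
  f <- ref_forces(x, v, 0)
  for (s in 1:2) {
    v_old <- v
    x <- (x + p$dt * v + 0.5 * p$dt^2 * f) %% matrix(L, 3, 3, byrow = TRUE)
    v_pred <- v_old + p$lambda * p$dt * f
    f_new <- ref_forces(x, v_pred, s)
    v <- v_old + 0.5 * p$dt * (f + f_new)
    f <- f_new
  }

  st <- simulation_state(pos, L, species, c(1L, 1L, 2L), bonds = bonds)
  st$velocities <- vel
  st2 <- integrate_steps(st, im, bp, p, 2, seed = seed)
  expect_equal(st2$positions, x, tolerance = 1e-12)
  expect_equal(st2$velocities, v, tolerance = 1e-12)
})

test_that("temperature estimator is exact and drift-invariant", {
  st <- solvent_fluid(5, seed = 8)
  v <- st$velocities
  expect_equal(instantaneous_temperature(matrix(0, 10, 3)), 0)
  # direct formula on centered velocities
  vc <- sweep(v, 2, colMeans(v))
  expect_equal(instantaneous_temperature(v),
               sum(vc^2) / (3 * (nrow(v) - 1)))
  # adding a uniform drift changes nothing
  expect_equal(instantaneous_temperature(sweep(v, 2, c(3, -1, 2), `+`)),
               instantaneous_temperature(v))
  expect_error(instantaneous_temperature(matrix(0, 1, 3)), "at least 2")
  # a large Maxwell-Boltzmann sample reads back its temperature
  set.seed(9)
  vbig <- random_velocities(10000, kT = 1)
  expect_equal(instantaneous_temperature(vbig), 1, tolerance = 0.02)
})

test_that("momentum is conserved by the pairwise forces", {
  st <- solvent_fluid(6, seed = 4)
  traj <- run_dpd(st, default_interaction_matrix(), n_steps = 1000,
                  snapshot_interval = 1000, thermo_interval = 250, seed = 5)
  drift <- abs(traj$thermo[, c("px", "py", "pz")]) / n_beads(st)
  expect_lt(max(drift), 1e-8)
})

test_that("trajectory recording and restart are exact", {
  st <- solvent_fluid(4, seed = 2)
  im <- default_interaction_matrix()
  # frame counting convention: entry frame + every interval
  traj <- run_dpd(st, im, n_steps = 10, snapshot_interval = 5, seed = 3)
  expect_equal(n_frames(traj), 3)
  expect_equal(vapply(traj$frames, `[[`, numeric(1), "step"), c(0, 5, 10))

  # observers fire for each recorded frame even when empty list works
  seen <- integer(0)
  traj2 <- run_dpd(st, im, n_steps = 10, snapshot_interval = 5, seed = 3,
                   observers = list(function(s, step) {
                     seen <<- c(seen, step)
                   }))
  expect_equal(seen, c(0, 5, 10))

  # a checkpointed state (with forces) continues the unbroken run exactly
  full <- run_dpd(st, im, n_steps = 100, snapshot_interval = 50, seed = 7)
  part1 <- run_dpd(st, im, n_steps = 50, snapshot_interval = 50, seed = 7)
  part2 <- run_dpd(part1$state, im, n_steps = 50, snapshot_interval = 50,
                   seed = 7)
  expect_identical(part2$state$positions, full$state$positions)
  expect_identical(part2$state$velocities, full$state$velocities)
})

test_that("a preformed bilayer patch stays intact", {
  L <- 10
  st <- bilayer_patch(L, L, L, seed = 6)
  n_lipids <- sum(st$molecule_species == "lecithin")
  im <- default_interaction_matrix()
  p <- dpd_params()
  st <- pre_equilibrate(st, im, bond_params(), p, n_steps = 200, seed = 6)
  traj <- run_dpd(st, im, n_steps = 20000, snapshot_interval = 5000,
                  thermo_interval = 5000, seed = 6)
  fin <- traj$state
  # periodic mid-plane from the tail-bead cloud (the patch may drift)
  idx <- which(fin$species == "L3")
  z <- fin$positions[idx, 3]
  th <- 2 * pi * z / L
  mid <- (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) / (2 * pi) * L
  dz <- z - mid
  dz <- dz - round(dz / L) * L
  # a lipid counts as shed when a terminal tail bead sits beyond the
  # membrane core (half-thickness = beads_per_lipid / (3 * area_per_lipid))
  # plus a 1.5 rc head/interface margin
  half_core <- 8 / 3 / (L * L / n_lipids * 2)
  bead_in_lipid <- (idx - 1) %% 8 + 1
  term <- bead_in_lipid %in% c(5, 8)
  shed <- tapply(abs(dz[term]) > half_core + 1.5,
                 fin$molecule_id[idx][term], any)
  expect_lt(mean(shed), 0.01)
  # thermostat held during the run
  expect_equal(mean(traj$thermo[, "kT"]), 1, tolerance = 0.05)
})
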