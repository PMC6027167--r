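test_that("concentration calibration follows V = n / (N_A c)", {
  v <- volume_from_calibration(50, 6)
  expect_equal(v, 1.384e4, tolerance = 1e-3)
  # the four chain counts share one box: same volume from each pair
  expect_equal(volume_from_calibration(200, 24), v)
  expect_equal(volume_from_calibration(100, 12), v)
  expect_error(volume_from_calibration(0, 6))
  expect_error(volume_from_calibration(50, -1))
})

test_that("concentration_of inverts the calibration to machine precision", {
  box <- calibrated_box()
  expect_equal(concentration_of(50, box), 6, tolerance = 1e-12)
  expect_equal(concentration_of(100, box), 12, tolerance = 1e-12)
  expect_equal(concentration_of(150, box), 18, tolerance = 1e-12)
  expect_equal(concentration_of(200, box), 24, tolerance = 1e-12)
  expect_identical(concentration_of(0, box), 0)
  # proportionality: doubled volume halves the concentration
  box2 <- box_spec(box$lengths * 2^(1 / 3), box$length_scale)
  expect_equal(concentration_of(100, box2), 6, tolerance = 1e-12)
})

test_that("vesicle builder places leaflets on concentric spheres", {
  cfg <- build_config(vesicle_radius = 10, bilayer_thickness = 2,
                      area_per_lipid = 1.0, n_capsaicin = 0, n_chitosan = 0,
                      box = box_spec(26))
  ms <- build_vesicle(cfg)
  lip_sizes <- table(ms$molecule_id)
  n_outer_expected <- round(4 * pi * 100 / 1.0)  # 1257
  n_inner_expected <- round(4 * pi * 64 / 1.0)
  expect_equal(length(lip_sizes), n_outer_expected + n_inner_expected)
  expect_equal(n_outer_expected, 1257)

  # head beads lie within [R_in - 0.5, R_out + 0.5]
  heads <- ms$positions[ms$species == "L1", , drop = FALSE]
  r <- sqrt(rowSums(sweep(heads, 2, rep(13, 3))^2))
  expect_true(all(r >= 8 - 0.5 & r <= 10 + 0.5))

  # tails start from their leaflet's head sphere toward the bilayer
  # interior: first tail beads sit strictly between the two head spheres
  idx_l3 <- which(ms$species == "L3")
  first_tail <- ms$positions[idx_l3[idx_l3 %% 8 %in% c(3, 6)], ,
                             drop = FALSE]
  rt <- sqrt(rowSums(sweep(first_tail, 2, rep(13, 3))^2))
  expect_true(all(rt > 8 - 2 & rt < 10 + 0.1))

  expect_error(build_config(vesicle_radius = 0, bilayer_thickness = 2),
               "vesicle_radius")
  expect_error(build_config(vesicle_radius = 10, bilayer_thickness = 2,
                            area_per_lipid = 0), "area_per_lipid")
  expect_error(build_config(vesicle_radius = 10, bilayer_thickness = 2,
                            box = box_spec(12)), "clearance")
})

test_that("solutes are scattered outside the vesicle", {
  cfg <- build_config(vesicle_radius = 5, bilayer_thickness = 2.5,
                      n_capsaicin = 10, n_chitosan = 2, box = box_spec(16),
                      rng_seed = 11)
  set.seed(cfg$rng_seed)
  sol <- scatter_solutes(cfg)
  expect_equal(nrow(sol$positions), 10 * 3 + 2 * 50)
  expect_equal(sum(sol$molecule_species == "capsaicin"), 10)
  expect_equal(sum(sol$molecule_species == "chitosan"), 2)
  # every solute bead outside the vesicle radius at t = 0
  d <- sweep(sol$positions, 2, rep(8, 3))
  for (k in 1:3) d[, k] <- d[, k] - round(d[, k] / 16) * 16
  expect_true(all(sqrt(rowSums(d^2)) > 5))

  cfg0 <- build_config(vesicle_radius = 5, bilayer_thickness = 2.5,
                       n_capsaicin = 0, n_chitosan = 0, box = box_spec(16))
  sol0 <- scatter_solutes(cfg0)
  expect_equal(nrow(sol0$positions), 0)
})

test_that("solvent fill hits the target density exactly", {
  ms <- dpdvesicle:::empty_molecule_set()
  box <- box_spec(10)
  set.seed(5)
  filled <- fill_solvent(ms, box, 3)
  expect_equal(nrow(filled$positions), 3000)
  expect_true(all(filled$species == "W"))
  expect_error(fill_solvent(ms, box, -3), "positive")
  # target below current count
  big <- fill_solvent(dpdvesicle:::empty_molecule_set(), box, 3)
  expect_error(fill_solvent(big, box, 0.001), "exceeded")
})

test_that("built systems have exact density and species partition", {
  cfg <- build_config(vesicle_radius = 5, bilayer_thickness = 2.5,
                      area_per_lipid = 1.2, n_capsaicin = 7, n_chitosan = 2,
                      box = box_spec(14), rng_seed = 2)
  st <- build_system(cfg)
  expect_equal(n_beads(st), round(3 * 14^3))
  expect_equal(number_density(st), 3, tolerance = 1 / n_beads(st))

  n_lip <- sum(st$molecule_species == "lecithin")
  expect_equal(sum(st$species %in% c("L1", "L2", "L3")), n_lip * 8)
  expect_equal(sum(st$species %in% c("C1", "C2", "C3")), 7 * 3)
  expect_equal(sum(st$species %in% c("G", "A")), 2 * 50)
  expect_equal(sum(st$species == "W"),
               n_beads(st) - n_lip * 8 - 21 - 100)

  # determinism: same seed gives bitwise-identical states
  st2 <- build_system(cfg)
  expect_identical(st2$positions, st$positions)

  # different seed changes placement but not counts
  cfg3 <- cfg
  cfg3$rng_seed <- 99L
  st3 <- build_system(cfg3)
  expect_equal(n_beads(st3), n_beads(st))
  expect_equal(table(st3$species), table(st$species))
  expect_false(identical(st3$positions, st$positions))
})

test_that("zero-solute config yields a pure vesicle in solvent", {
  cfg <- build_config(vesicle_radius = 5, bilayer_thickness = 2.5,
                      n_capsaicin = 0, n_chitosan = 0, box = box_spec(14),
                      rng_seed = 3)
  st <- build_system(cfg)
  expect_setequal(unique(st$species), c("L1", "L2", "L3", "W"))
  expect_equal(n_beads(st), round(3 * 14^3))
})
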