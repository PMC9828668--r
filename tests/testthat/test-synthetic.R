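test_that("integrated true volume matches the analytic helix for constant cross-sections", {
  sp <- helix_spec(flagellum_length_um = 100,
                   base_flagellum_diameter_um = 0.3,
                   tip_flagellum_diameter_um = 0.3,
                   midpiece_fraction = 0.8,
                   base_minor_axis_um = 0.1, tip_minor_axis_um = 0.1,
                   base_major_axis_um = 0.2, tip_major_axis_um = 0.2,
                   pitch_base_um = 2.5, pitch_tip_um = 2.5)
  v <- true_helix_volume(sp)
  n_g <- floor(80 / 2.5)
  r <- 0.3 / 2 + 0.1 / 2
  arc_per_gyre <- sqrt(2.5^2 + (2 * pi * r)^2)
  analytic <- pi * 0.1 * 0.05 * n_g * arc_per_gyre
  expect_lt(abs(v - analytic) / analytic, 1e-6)
})

test_that("the volume integral converges and is deterministic", {
  sp <- helix_spec()
  v1 <- true_helix_volume(sp, n_steps = 1000)
  v2 <- true_helix_volume(sp, n_steps = 4000)
  expect_lt(abs(v2 - v1) / v2, 1e-6)
  expect_identical(true_helix_volume(sp), true_helix_volume(sp))
  expect_error(true_helix_volume(sp, n_steps = 10), "1000")
})

test_that("volume vanishes as the midpiece fraction shrinks", {
  vols <- vapply(c(0.8, 0.4, 0.2, 0.1),
                 function(f) true_helix_volume(helix_spec(midpiece_fraction = f)),
                 numeric(1))
  expect_true(all(diff(vols) < 0))
  expect_lt(vols[4] / vols[1], 0.2)
})

test_that("noise-free projection recovers the local minor axis exactly", {
  sp <- helix_spec()
  cell <- project_measurements(sp, noise_spec(cv = 0))
  pr <- helixvol:::helix_profiles(sp)
  m <- cell$measurements
  for (g in unique(m$gyre_index)) {
    for (h in 1:2) {
      f <- m[m$kind == "flagellum_width" & m$gyre_index == g & m$half == h, ]
      p <- m[m$kind == "flagellum_plus_minor" & m$gyre_index == g &
               m$half == h, ]
      expect_equal(minor_axis_diameter(p$value_um, f$value_um),
                   pr$b(f$center_position_um), tolerance = 1e-12)
    }
  }
})

test_that("a cell missing every major axis cannot be assembled", {
  cell <- project_measurements(helix_spec(), noise_spec(cv = 0))
  m <- cell$measurements
  m$value_um[m$kind == "major_axis"] <- NA
  m$obscured[m$kind == "major_axis"] <- TRUE
  cell$measurements <- m
  expect_error(assemble_gyre_geometries(cell), "cannot impute")
})

test_that("measurement noise cv controls the spread of repeated projections", {
  cv <- 0.02
  vals <- replicate(400, {
    cell <- project_measurements(helix_spec(), noise_spec(cv = cv))
    cell$measurements$value_um[1]
  })
  expect_equal(sd(log(vals)), sqrt(log(1 + cv^2)), tolerance = 0.15)
})

test_that("simulated Yule trees are ultrametric, unit height, seeded", {
  tr <- simulate_tree(3, seed = 5)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(1, 3), tolerance = 1e-10)

  t1 <- ape::write.tree(simulate_tree(12, seed = 9))
  t2 <- ape::write.tree(simulate_tree(12, seed = 9))
  expect_identical(t1, t2)
  t3 <- ape::write.tree(simulate_tree(12, seed = 10))
  expect_false(identical(t1, t3))

  big <- simulate_tree(55, seed = 1)
  expect_identical(ape::Ntip(big), 55L)
  expect_identical(big$Nnode, 54L)
  expect_error(simulate_tree(2), "3")
})

test_that("species trait covariance follows the lambda mixture", {
  tr <- simulate_tree(6, seed = 3)
  # lambda_true = 0: off-diagonal sample covariance vanishes over replicates
  spec0 <- comparative_spec(n_species = 6, lambda_true = 0, bm_sd = 0.3)
  reps <- replicate(400, {
    log(simulate_species_traits(tr, spec0)$flagellum_um)
  })
  S <- stats::cov(t(reps))
  offdiag <- S[upper.tri(S)]
  expect_lt(max(abs(offdiag)), 0.3^2 * 0.25)   # ~0 vs diagonal 0.09
  expect_equal(mean(diag(S)), 0.09, tolerance = 0.3)

  # lambda_true = 1: off-diagonals match the scaled tree covariance
  spec1 <- comparative_spec(n_species = 6, lambda_true = 1, bm_sd = 0.3)
  reps1 <- replicate(400, {
    log(simulate_species_traits(tr, spec1)$flagellum_um)
  })
  S1 <- stats::cov(t(reps1))
  Ctheo <- 0.09 * phylo_covariance(tr)$C
  expect_lt(max(abs(S1 - Ctheo)), 0.05)
})

test_that("zero-rate traits collapse to the root value", {
  tr <- simulate_tree(5, seed = 4)
  spec <- comparative_spec(n_species = 5, bm_sd = 1e-9,
                           allometry_resid_sd = 1e-9)
  tr8 <- simulate_species_traits(tr, spec)
  expect_equal(tr8$flagellum_um, rep(110, 5), tolerance = 1e-4)
})

test_that("repeat-measure generator hits its variance-ratio targets", {
  sim0 <- simulate_repeat_measures(cv = 0, seed = 1)
  byp <- split(sim0$data$value, sim0$data$point_id)
  expect_true(all(vapply(byp, function(v) all(v == v[1]), logical(1))))
  expect_identical(sim0$truth$icc, 1)

  tv <- rep(c(9, 10, 11, 10.5, 9.5), 4)
  sim <- simulate_repeat_measures(tv, cv = 0.05, n_repeats = 3, seed = 2)
  expect_equal(sim$truth$icc,
               var(tv - mean(tv)) /
                 (var(tv - mean(tv)) + mean((tv * 0.05)^2)))

  # default protocol is tuned near the observed repeatability of 0.998
  sim_def <- simulate_repeat_measures(seed = 6)
  expect_gt(sim_def$truth$icc, 0.99)
})

test_that("generated bundles are seed-deterministic and reader round-trippable", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  spec <- comparative_spec(n_species = 10, seed = 77)
  b1 <- generate_dataset(d1, spec)
  b2 <- generate_dataset(d2, spec)
  for (f in c("measurements.csv", "cells.csv", "species.csv", "tree.nwk",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_length(b1$study$truth$true_volumes_um3, 10)
  expect_true(all(b1$study$truth$true_volumes_um3 > 0))

  meas <- read_measurements(file.path(d1, "measurements.csv"))
  cells_df <- read_cells(file.path(d1, "cells.csv"))
  cells <- assemble_cells(meas, cells_df)
  expect_length(cells, 10)
  orig <- b1$study$cells[[3]]
  back <- cells[[orig$cell_id]]
  expect_equal(back$measurements$value_um, orig$measurements$value_um)
  expect_equal(back$midpiece_um, orig$midpiece_um)
  tr <- read_tree_file(file.path(d1, "tree.nwk"),
                       species = cells_df$species)
  expect_identical(sort(tr$tip.label), sort(cells_df$species))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noise-free bundle volumes track the generator's per-cell targets", {
  spec <- comparative_spec(n_species = 8, seed = 21,
                           flag_sd_resid = 1e-9, minor_sd_resid = 1e-9,
                           major_sd_resid = 1e-9, gyre_sd_resid = 1e-9)
  st <- simulate_study(spec)
  est <- vapply(st$cells, function(cl) cell_volume(cl)$total_volume_um3,
                numeric(1))
  tru <- st$truth$true_volumes_um3[vapply(st$cells, `[[`, "", "species")]
  expect_equal(unname(est), unname(tru), tolerance = 1e-6)
})
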