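test_that("minor axis comes from subtraction and rejects inconsistent pairs", {
  expect_equal(minor_axis_diameter(0.45, 0.30), 0.15)
  expect_equal(minor_axis_diameter(0.30, 0.30), 0)
  expect_error(minor_axis_diameter(0.29, 0.30), "inconsistent")
  expect_error(minor_axis_diameter(0, 0.30), "positive")
})

test_that("elliptical area, circumference and helical length follow their closed forms", {
  expect_equal(ellipse_cross_section_area(0.2, 0.1), 0.0157079632679,
               tolerance = 1e-10)
  expect_equal(ellipse_cross_section_area(0.2, 0.2), pi * 0.01)
  expect_equal(ellipse_cross_section_area(0.7, 0), 0)
  expect_error(ellipse_cross_section_area(-0.1, 0.1), "non-negative")

  expect_equal(flagellum_circumference(0.30), 0.942477796077, tolerance = 1e-10)
  expect_equal(flagellum_circumference(0), 0)
  expect_equal(flagellum_circumference(1 / pi), 1)

  expect_equal(helical_segment_length(3, 4), 5)
  expect_equal(helical_segment_length(7.3, 0), 7.3)
  # frozen by direct arithmetic: sqrt(2.5^2 + 0.9424778^2)
  expect_equal(helical_segment_length(2.5, 0.9424778), 2.6717530581,
               tolerance = 1e-9)
  g <- runif(10, 0, 5); cc <- runif(10, 0, 2)
  expect_true(all(helical_segment_length(g, cc) >= pmax(g, cc)))
})

test_that("gyre intervals are centre-point differences of corresponding measures", {
  cell <- make_constant_cell(n_gyres = 3, pitch = 2.5)
  # shift third gyre to make intervals 2.5 then 2.6
  m <- cell$measurements
  m$center_position_um[m$gyre_index == 3] <-
    m$center_position_um[m$gyre_index == 3] + 0.1
  cell$measurements <- m
  iv <- gyre_intervals(cell)
  expect_equal(iv$interval_um, c(2.5, 2.6))

  one <- make_constant_cell(n_gyres = 5)
  one$measurements <- one$measurements[one$measurements$gyre_index == 1, ]
  expect_error(gyre_intervals(one), "insufficient gyres")

  # noise-free synthetic cell with constant pitch p recovers p exactly
  sp <- helix_spec(pitch_base_um = 3.1, pitch_tip_um = 3.1)
  synth <- project_measurements(sp, noise_spec(cv = 0))
  expect_equal(gyre_intervals(synth)$interval_um,
               rep(3.1, length(gyre_intervals(synth)$interval_um)),
               tolerance = 1e-12)
})

test_that("gyre assembly imputes missing components from cell means and records it", {
  cell <- make_constant_cell(n_gyres = 4)
  gg <- assemble_gyre_geometries(cell)
  expect_true(all(lengths(gg$imputed_fields) == 0))

  m <- cell$measurements
  m$value_um[m$gyre_index == 3 & m$kind == "major_axis"] <- NA
  m$obscured[m$gyre_index == 3 & m$kind == "major_axis"] <- TRUE
  # make the other majors distinguishable: mean of 0.18, 0.24, 0.21 = 0.21
  m$value_um[m$gyre_index == 1 & m$kind == "major_axis"] <- 0.18
  m$value_um[m$gyre_index == 2 & m$kind == "major_axis"] <- 0.24
  m$value_um[m$gyre_index == 4 & m$kind == "major_axis"] <- 0.21
  cell$measurements <- m
  gg2 <- assemble_gyre_geometries(cell)
  expect_equal(gg2$major_axis_um[3], 0.21)
  expect_equal(gg2$imputed_fields[[3]], "major_axis_um")

  m$value_um[m$kind == "major_axis"] <- NA
  m$obscured[m$kind == "major_axis"] <- TRUE
  cell$measurements <- m
  expect_error(assemble_gyre_geometries(cell), "cannot impute")
})

test_that("gyre volume is area times helical length and is linear in the minor axis", {
  g <- list(gyre_interval_um = 2.5, mean_flagellum_diameter_um = 0.30,
            mean_minor_axis_um = 0.1, major_axis_um = 0.2)
  expect_equal(gyre_volume(g), 0.041967798876, tolerance = 1e-9)
  g0 <- g; g0$mean_minor_axis_um <- 0
  expect_equal(gyre_volume(g0), 0)
  g2 <- g; g2$mean_minor_axis_um <- 0.2
  expect_equal(gyre_volume(g2), 2 * gyre_volume(g), tolerance = 1e-12)
})

test_that("missing-gyre counts round half-up from the obscured length", {
  expect_identical(estimate_missing_gyre_count(5.0, 2.5), 2L)
  expect_identical(estimate_missing_gyre_count(0, 2.5), 0L)
  expect_identical(estimate_missing_gyre_count(6.3, 2.5), 3L)  # 2.52 -> 3
  expect_identical(estimate_missing_gyre_count(6.25, 2.5), 3L) # half-up
  expect_error(estimate_missing_gyre_count(5, 0), "positive")
})

test_that("cell volume matches the constant-cell closed form to 1e-9 relative", {
  n <- 7; d <- 0.31; minr <- 0.12; maj <- 0.22; p <- 3.4
  cell <- make_constant_cell(n, d, minr, maj, p)
  cv <- cell_volume(cell)
  expect_equal(cv$n_measured_gyres, n)
  closed <- constant_cell_volume_closed_form(n, d, minr, maj, p)
  expect_lt(abs(cv$total_volume_um3 - closed) / closed, 1e-9)
})

test_that("obscured sections add mean per-gyre volume for the estimated missing gyres", {
  n <- 6; p <- 2.5
  base <- make_constant_cell(n, pitch = p)
  with_gap <- make_constant_cell(n, pitch = p,
                                 obscured_sections = 2 * p)
  v0 <- cell_volume(base)
  v1 <- cell_volume(with_gap)
  expect_identical(v1$n_estimated_missing_gyres, 2L)
  expect_equal(v1$total_volume_um3, (n + 2) / n * v0$total_volume_um3,
               tolerance = 1e-12)
  # invariant: total = sum(per-gyre) + missing * mean(per-gyre)
  expect_equal(v1$total_volume_um3,
               sum(v1$per_gyre_volumes_um3) +
                 v1$n_estimated_missing_gyres * mean(v1$per_gyre_volumes_um3))
})

test_that("imputing a value equal to the cell mean leaves the total unchanged", {
  cell <- make_constant_cell(5)
  v0 <- cell_volume(cell)$total_volume_um3
  m <- cell$measurements
  pick <- m$gyre_index == 2 & m$kind == "major_axis"
  m$value_um[pick] <- NA
  m$obscured[pick] <- TRUE
  cell$measurements <- m
  v1 <- cell_volume(cell)$total_volume_um3
  expect_equal(v1, v0, tolerance = 1e-12)
})

test_that("volume scales as the cube of a uniform length rescaling", {
  for (k in c(0.5, 2, 3.7)) {
    a <- make_constant_cell(5, d = 0.3, minr = 0.1, maj = 0.2, pitch = 2.5)
    b <- make_constant_cell(5, d = 0.3 * k, minr = 0.1 * k, maj = 0.2 * k,
                            pitch = 2.5 * k)
    expect_equal(cell_volume(b)$total_volume_um3,
                 k^3 * cell_volume(a)$total_volume_um3, tolerance = 1e-9)
  }
})

test_that("volume increases strictly in minor axis, major axis, gyre count and interval", {
  base <- list(n = 5, d = 0.3, minr = 0.1, maj = 0.2, p = 2.5)
  vol <- function(n, minr, maj, p) {
    cell_volume(make_constant_cell(n, base$d, minr, maj, p))$total_volume_um3
  }
  v0 <- vol(base$n, base$minr, base$maj, base$p)
  expect_gt(vol(base$n, base$minr * 1.2, base$maj, base$p), v0)
  expect_gt(vol(base$n, base$minr, base$maj * 1.2, base$p), v0)
  expect_gt(vol(base$n + 1, base$minr, base$maj, base$p), v0)
  expect_gt(vol(base$n, base$minr, base$maj, base$p * 1.2), v0)
})

test_that("cell record validation catches schema violations", {
  cell <- make_constant_cell(3)
  m <- cell$measurements
  m$value_um[m$kind == "flagellum_plus_minor"][1] <- 0.1  # < flagellum width
  expect_error(
    cell_record("x", "sp", "f", m, midpiece_um = 10, tail_um = 5),
    "combined width"
  )
  m2 <- cell$measurements
  m2 <- rbind(m2, m2[m2$kind == "major_axis", ][1, ])
  expect_error(
    cell_record("x", "sp", "f", m2, midpiece_um = 10, tail_um = 5),
    "major-axis"
  )
  expect_error(
    cell_record("x", "sp", "f", cell$measurements, midpiece_um = 0,
                tail_um = 0),
    "positive"
  )
})
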