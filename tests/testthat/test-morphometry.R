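# Angles, polarity indexes, rings, profiles, extraction and distances.

test_that("bead-axis groove orientation covers the canonical geometries", {
  b <- c(0, 0, 0)
  expect_equal(groove_orientation_bead(c(5, 0, 0), b, c(2, 0, 0)), 0)
  expect_equal(groove_orientation_bead(c(5, 0, 0), b, c(-1, 0, 0)), 180)
  expect_equal(groove_orientation_bead(c(5, 0, 0), b, c(0, 3, 0)), 90)
  expect_error(groove_orientation_bead(b, b, c(1, 0, 0)), "degenerate")
})

test_that("orientation classification uses closed-lower-bin convention", {
  expect_equal(classify_orientation(30), "Polarized")
  expect_equal(classify_orientation(0), "Polarized")
  expect_equal(classify_orientation(45), "Polarized")
  expect_equal(classify_orientation(45.0001), "Central")
  expect_equal(classify_orientation(135), "Central")
  expect_equal(classify_orientation(135.0001), "Antipolarized")
  expect_equal(classify_orientation(180), "Antipolarized")
  expect_error(classify_orientation(190), "0, 180")

  # partition completeness: every angle maps to exactly one category
  sweep <- classify_orientation(seq(0, 180, by = 0.5))
  expect_false(any(is.na(sweep)))
  expect_equal(sort(unique(sweep)),
               c("Antipolarized", "Central", "Polarized"))
})

test_that("dish orientation and lobe rotation follow their conventions", {
  cell <- c(5, 5, 4)
  expect_equal(groove_orientation_dish(cell, c(5, 5, 1), 0), 0)
  expect_equal(groove_orientation_dish(cell, c(5, 5, 7), 0), 180)
  expect_equal(groove_orientation_dish(cell, c(8, 5, 4), 0), 90)
  expect_error(groove_orientation_dish(c(5, 5, 0), c(5, 5, 1), 0), "plane")

  expect_equal(lobe_rotation(list(c(0, 0, 1), c(0, 3, 1)))$angle_deg, 0)
  expect_equal(lobe_rotation(list(c(0, 0, 1), c(0, 0, 4)))$angle_deg, 90)
  ap30 <- list(c(0, 0, 0), c(0, cos(pi / 6), sin(pi / 6)))
  expect_equal(lobe_rotation(ap30)$angle_deg, 30, tolerance = 1e-9)
  expect_error(lobe_rotation(list(c(1, 1, 1), c(1, 1, 1))), "coincident")
})

test_that("polarity index fixed points, sign and clamping", {
  cell <- c(0, 0, 0); bead <- c(5, 0, 0)
  expect_equal(polarity_index(bead, cell, bead)$index, 1.0)
  expect_equal(polarity_index(cell, cell, bead)$index, 0.0)
  expect_equal(polarity_index(-bead, cell, bead)$index, -1.0)
  # off-axis target: projection only
  expect_equal(polarity_index(c(2.5, 4, 0), cell, bead)$index, 0.5)
  # clamped when the projection overshoots the bead
  expect_equal(polarity_index(c(7, 0, 0), cell, bead)$index, 1.0)
  expect_equal(polarity_index(c(-9, 0, 0), cell, bead)$index, -1.0)
  expect_error(polarity_index(bead, cell, cell), "degenerate")
  # projection point reported on the axis
  pr <- polarity_index(c(2.5, 4, 0), cell, bead)
  expect_equal(pr$projection, c(2.5, 0, 0))
})

test_that("lamp ring fraction: limits and 2d mode", {
  v <- array(0, c(11, 40, 40))
  v[6, 20, 20] <- 100                      # at (x,y,z) = (2.925, 2.925, 1.1)
  st <- stack_of(v, "lamp1", voxel = c(0.2, 0.15, 0.15))
  p <- c(19.5 * 0.15, 19.5 * 0.15, 5.5 * 0.2)
  expect_equal(lamp_ring_fraction(st, p, 1), 1.0)
  expect_equal(lamp_ring_fraction(st, p + c(3, 0, 0), 1), 0.0)
  expect_equal(lamp_ring_fraction(st, p, 1, mode = "2d"), 1.0)
  v0 <- array(0, c(2, 4, 4))
  expect_warning(expect_true(is.na(
    lamp_ring_fraction(stack_of(v0, "lamp1"), p, 1))), "zero total")
})

test_that("z distribution normalises to 100 and localises signal", {
  v <- array(1, c(12, 10, 10))
  st <- stack_of(v, "lamp1", voxel = c(0.2, 0.15, 0.15))
  zd <- z_distribution(st, "lamp1", synapse_z = 0)
  expect_equal(zd, rep(10, 10), tolerance = 1e-12)
  expect_equal(sum(zd), 100, tolerance = 1e-9)

  v2 <- array(0, c(12, 10, 10)); v2[1, , ] <- 5
  zd2 <- z_distribution(stack_of(v2, "bcr", voxel = c(0.2, 0.15, 0.15)),
                        "bcr", synapse_z = 0)
  expect_equal(zd2, c(100, rep(0, 9)))

  expect_warning(zna <- z_distribution(stack_of(array(0, c(12, 4, 4)), "bcr",
                                                voxel = c(0.2, 0.15, 0.15)),
                                       "bcr", 0), "no signal")
  expect_true(all(is.na(zna)))
})

test_that("lysosome cluster position relative to the perinuclear region", {
  vox <- c(0.2, 0.15, 0.15)
  nuc <- array(FALSE, c(20, 40, 40))
  nuc[5:15, 10:25, 10:25] <- TRUE
  lamp_near <- array(FALSE, dim(nuc)); lamp_near[8:10, 27:29, 12:14] <- TRUE
  lamp_far <- array(FALSE, dim(nuc)); lamp_far[8:10, 36:38, 34:36] <- TRUE
  nm <- mask3d(nuc, vox)
  expect_equal(cluster_position(mask3d(lamp_near, vox), nm, 1), "inside")
  expect_equal(cluster_position(mask3d(lamp_far, vox), nm, 1), "outside")
  # straddling the margin by one voxel counts as inside
  straddle <- array(FALSE, dim(nuc))
  straddle[10, 26:31, 12] <- TRUE   # first voxel 0.15 um from the nucleus
  expect_equal(cluster_position(mask3d(straddle, vox), nm, 1), "inside")
  expect_warning(expect_true(is.na(
    cluster_position(mask3d(array(FALSE, dim(nuc)), vox), nm, 1))), "empty")
})

test_that("radial profile: uniform field, point source, Gaussian oracle", {
  vox <- c(0.2, 0.1, 0.1)
  v <- array(7, c(5, 60, 60))
  st <- stack_of(v, "exo70", voxel = vox)
  ref <- c(30 * 0.1, 30 * 0.1, 0.5)
  pr <- radial_profile(st, "exo70", ref, r_max_um = 2)
  expect_true(all(abs(pr$mfi - 7) < 1e-9))

  v2 <- array(0, c(5, 60, 60)); v2[3, 30, 30] <- 100
  pr2 <- radial_profile(stack_of(v2, "exo70", voxel = vox), "exo70",
                        c(29.5 * 0.1, 29.5 * 0.1, 0.5), r_max_um = 1.5)
  expect_true(all(diff(pr2$mfi) <= 1e-12))

  # Gaussian spot: disc MFI matches the closed-form average within 3%
  sigma <- 0.3; A <- 50
  yc <- (seq_len(60) - 0.5) * 0.1; xc <- yc
  d2 <- outer((yc - 3)^2, (xc - 3)^2, `+`)
  v3 <- array(0, c(5, 60, 60))
  v3[3, , ] <- A * exp(-d2 / (2 * sigma^2))
  pr3 <- radial_profile(stack_of(v3, "exo70", voxel = vox), "exo70",
                        c(3, 3, 0.5), r_max_um = 1.2, dr_um = 0.3)
  analytic <- function(r) A * (2 * sigma^2 / r^2) * (1 - exp(-r^2 / (2 * sigma^2)))
  expect_lt(max(abs(pr3$mfi / analytic(pr3$radius_um) - 1)), 0.03)

  expect_error(radial_profile(st, "exo70", c(99, 0, 0)), "outside")
})

test_that("antigen extraction percentages from bead time courses", {
  mk <- function(amp) {
    v <- array(0, c(6, 40, 40))
    idx <- which(v[1, , ] == 0, arr.ind = TRUE)
    disc <- (idx[, 1] - 20)^2 + (idx[, 2] - 20)^2 <= 36
    for (z in 2:4) { sl <- v[z, , ]; sl[idx[disc, ]] <- amp; v[z, , ] <- sl }
    stack_of(v, "ova", voxel = c(0.5, 0.2, 0.2))
  }
  b <- c(19.5 * 0.2, 19.5 * 0.2, 1.2)
  expect_equal(antigen_extraction_pct(list(mk(100), mk(100)), b, 2),
               c(0, 0), tolerance = 1e-9)
  expect_equal(antigen_extraction_pct(list(mk(100), mk(0)), b, 2),
               c(0, 100), tolerance = 1e-9)
  expect_equal(antigen_extraction_pct(list(mk(100), mk(75), mk(40)), b, 2),
               c(0, 25, 60), tolerance = 1e-6)
  expect_error(antigen_extraction_pct(list(), b), "t = 0")
})

test_that("surface MFI is linear in intensity and errors on empty regions", {
  v <- array(0, c(4, 20, 20)); v[2, 5:15, 5:15] <- 10
  st1 <- stack_of(v, "bcr"); st2 <- stack_of(2 * v, "bcr")
  region <- matrix(TRUE, 20, 20)
  expect_equal(surface_mfi(st2, "bcr", region) /
                 surface_mfi(st1, "bcr", region), 2)
  expect_equal(surface_mfi(stack_of(0 * v, "bcr"), "bcr", region), 0)
  expect_error(surface_mfi(st1, "bcr", matrix(FALSE, 20, 20)), "empty")
})

test_that("synapse centre distance is planar Euclidean", {
  expect_equal(synapse_center_distance(c(1, 2, 5), c(1, 2, 0)), 0)
  expect_equal(synapse_center_distance(c(0, 0, 3), c(3, 4, 9)), 5)
})
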