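# Masks, labelled regions, morphology, centres of mass and overlaps.

vox_iso <- c(0.2, 0.2, 0.2)

ball_mask <- function(dm, center_px, r_px, voxel = vox_iso) {
  a <- array(FALSE, dm)
  idx <- which(!a, arr.ind = TRUE)
  d2 <- (idx[, 1] - center_px[1])^2 + (idx[, 2] - center_px[2])^2 +
    (idx[, 3] - center_px[3])^2
  a[idx[d2 <= r_px^2, ]] <- TRUE
  mask3d(a, voxel)
}

test_that("threshold segmentation is strict, deterministic, warns on empty", {
  v <- array(0, c(4, 6, 6)); v[2, 3, 3] <- 10; v[3, 4, 4] <- 5
  st <- stack_of(v, "nucleus")
  m <- segment_channel(st, "nucleus", "fixed", list(threshold = 5))
  expect_equal(sum(m$voxels), 1)          # strictly greater than
  expect_true(m$voxels[2, 3, 3])
  expect_warning(empty <- segment_channel(st, "nucleus", "fixed",
                                          list(threshold = 99)), "empty")
  expect_equal(sum(empty$voxels), 0)
  m2 <- segment_channel(st, "nucleus", "fixed", list(threshold = 5))
  expect_identical(m$voxels, m2$voxels)
  # pluggable classifier function
  mf <- segment_channel(st, "nucleus", function(vol, params) vol > 7)
  expect_equal(sum(mf$voxels), 1)
})

test_that("otsu segmentation recovers the nucleus volume on phantoms", {
  cfg <- test_config(seed = 21, on = "nucleus")
  sc <- make_scene(cfg)
  st <- render_stack(sc, cfg)
  m <- segment_channel(st, "nucleus", "otsu")
  expect_lt(abs(mask_volume(m) / sc$nucleus_volume_true - 1), 0.05)

  cfgn <- test_config(seed = 22, noise = TRUE, on = "nucleus")
  stn <- render_stack(make_scene(cfgn), cfgn)
  mn <- segment_channel(stn, "nucleus", "otsu")
  expect_lt(abs(mask_volume(mn) / sc$nucleus_volume_true - 1), 0.10)
})

test_that("connected components: ordering, counts and connectivity", {
  a <- array(FALSE, c(6, 12, 12))
  a[2:4, 2:5, 2:5] <- TRUE          # 48 voxels
  a[5, 9:10, 9:10] <- TRUE          # 4 voxels
  regs <- connected_components(mask3d(a, vox_iso), 6)
  expect_equal(nrow(regs$table), 2)
  expect_equal(regs$table$voxel_count, c(48, 4))
  expect_equal(regs$table$label, c(1, 2))   # label 1 is the largest
  expect_equal(regs$table$volume_um3, c(48, 4) * prod(vox_iso))

  # diagonal voxel pair: separate under 6-, joined under 26-connectivity
  b <- array(FALSE, c(2, 2, 2)); b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE
  expect_equal(nrow(connected_components(mask3d(b, vox_iso), 6)$table), 2)
  expect_equal(nrow(connected_components(mask3d(b, vox_iso), 26)$table), 1)
  # in-plane diagonal pair
  d <- array(FALSE, c(1, 2, 2)); d[1, 1, 1] <- TRUE; d[1, 2, 2] <- TRUE
  expect_equal(nrow(connected_components(mask3d(d, vox_iso), 6)$table), 2)
  expect_equal(nrow(connected_components(mask3d(d, vox_iso), 26)$table), 1)
})

test_that("morphology: identity, shells, disc growth and monotonicity", {
  m <- ball_mask(c(9, 31, 31), c(5, 16, 16), 10)
  expect_identical(morph_op(m, "erode", 0)$voxels, m$voxels)

  # one-pixel-thick shell erodes to nothing (per slice)
  er <- morph_op(m, "erode", 1)
  shell <- mask3d(m$voxels & !er$voxels, vox_iso)
  expect_equal(sum(morph_op(shell, "erode", 1)$voxels), 0)

  # disc of radius 10 dilated by 2 matches a rasterized radius-12 disc
  disc <- array(FALSE, c(1, 31, 31))
  idx <- which(!disc, arr.ind = TRUE)
  disc[idx[(idx[, 2] - 16)^2 + (idx[, 3] - 16)^2 <= 100, ]] <- TRUE
  d2 <- morph_op(mask3d(disc, vox_iso), "dilate", 2)
  ref <- (idx[, 2] - 16)^2 + (idx[, 3] - 16)^2 <= 144
  mismatch <- sum(xor(d2$voxels[idx], ref))
  expect_lt(mismatch / sum(ref), 0.1)    # within brush discretization

  # volume monotone under dilation, antitone under erosion
  expect_gte(mask_volume(morph_op(m, "dilate", 1)), mask_volume(m))
  expect_lte(mask_volume(morph_op(m, "erode", 1)), mask_volume(m))
  expect_true(all(m$voxels[morph_op(morph_op(m, "erode", 1), "dilate", 1)$voxels]))

  # 3D mode: dilation grows, erosion shrinks, across slices too
  d3 <- morph_op(m, "dilate", 1, mode = "3d")
  e3 <- morph_op(m, "erode", 1, mode = "3d")
  expect_true(all(d3$voxels[m$voxels]))
  expect_true(all(m$voxels[e3$voxels]))
  expect_gt(sum(d3$voxels), sum(m$voxels))
})

test_that("centre of mass: symmetry, point masses and intensity ramps", {
  m <- ball_mask(c(9, 21, 21), c(5, 11, 11), 6)
  cm <- center_of_mass(m)
  expect_equal(unname(cm), c(10.5 * 0.2, 10.5 * 0.2, 4.5 * 0.2),
               tolerance = 1e-9)

  v <- array(0, c(1, 1, 41))
  v[1, 1, 1] <- 7; v[1, 1, 21] <- 7      # equal masses at x=0.1 and x=4.1
  st <- stack_of(v, "x", voxel = vox_iso)
  expect_equal(unname(center_of_mass(st, "x", "intensity")[1]), 2.1)

  # linear ramp on [0, L]: intensity CM at 2L/3
  n <- 100
  ramp <- array(rep(seq_len(n), each = 1), c(1, 1, n))
  str <- stack_of(ramp, "r", voxel = c(0.2, 0.2, 0.1))
  L <- n * 0.1
  expect_lt(abs(center_of_mass(str, "r", "intensity")[1] - 2 * L / 3), 0.1)

  expect_error(center_of_mass(mask3d(array(FALSE, c(2, 2, 2)), vox_iso)),
               "empty region")
})

test_that("mask volume is voxel count times voxel volume", {
  a <- array(FALSE, c(20, 50, 50)); a[seq_len(1000)] <- TRUE
  expect_equal(mask_volume(mask3d(a, c(0.2, 0.07, 0.07))), 1000 * 0.2 * 0.07^2)
  expect_equal(mask_volume(mask3d(array(FALSE, c(2, 2, 2)), vox_iso)), 0)

  # rasterized 4-um sphere close to (4/3) pi r^3
  sph <- ball_mask(c(45, 45, 45), c(23, 23, 23), 20)
  expect_lt(abs(mask_volume(sph) / ((4 / 3) * pi * 4^3) - 1), 0.03)
})

test_that("mask intersection: idempotence, disjointness, nesting, shapes", {
  a <- ball_mask(c(9, 21, 21), c(5, 11, 11), 6)
  b <- ball_mask(c(9, 21, 21), c(5, 11, 11), 3)
  off <- ball_mask(c(9, 21, 21), c(2, 3, 3), 2)
  expect_identical(intersect_masks(a, a)$voxels, a$voxels)
  expect_identical(intersect_masks(a, b)$voxels, b$voxels)   # nested
  expect_equal(sum(intersect_masks(b, off)$voxels), 0)       # disjoint
  expect_lte(sum(intersect_masks(a, off)$voxels),
             min(sum(a$voxels), sum(off$voxels)))
  expect_error(intersect_masks(a, mask3d(array(FALSE, c(2, 2, 2)), vox_iso)),
               "shape mismatch")
})

test_that("overlap fraction: limits, tolerance monotonicity, half coverage", {
  lamin <- ball_mask(c(9, 41, 41), c(5, 21, 21), 12)
  everywhere <- mask3d(array(TRUE, dim(lamin$voxels)), vox_iso)
  nothing <- mask3d(array(FALSE, dim(lamin$voxels)), vox_iso)
  expect_equal(overlap_fraction_with_tolerance(lamin, everywhere), 1.0)
  expect_equal(overlap_fraction_with_tolerance(lamin, nothing), 0.0)

  # actin covering exactly the y > centre half
  half <- lamin$voxels
  half[, 1:21, ] <- FALSE
  actin <- mask3d(half, vox_iso)
  f <- overlap_fraction_with_tolerance(lamin, actin, erosion_px = 1,
                                       tolerance_px = 0)
  expect_lt(abs(f - 0.5), 0.05)

  # monotone non-decreasing in tolerance_px
  fr <- vapply(0:4, function(tp)
    overlap_fraction_with_tolerance(lamin, actin, 1, tp), 0)
  expect_true(all(diff(fr) >= -1e-12))

  thin <- mask3d(array(FALSE, dim(lamin$voxels)) , vox_iso)
  thin$voxels[5, 21, ] <- TRUE
  expect_warning(expect_true(is.na(
    overlap_fraction_with_tolerance(thin, actin, erosion_px = 2))),
    "empty after erosion")
})
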