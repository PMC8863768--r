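# Synthetic scene generator: configuration validation, analytic ground
# truth, rendering physics and determinism.

test_that("configuration invariants are validated with informative errors", {
  expect_error(scene_config(cell_radius = -1), "cell_radius")
  expect_error(scene_config(groove_depth_frac = 1.5), "groove_depth_frac")
  expect_error(scene_config(mtoc_offset = 2), "mtoc_offset")
  expect_error(scene_config(lobe_radii = c(2, 2.5, 3.2)), "share a radius")
  # nucleus that cannot fit in the cell
  expect_error(scene_config(cell_radius = 3, lobe_radii = c(2, 2, 3.2)),
               "larger than cell")
  # groove deeper than the frontal lobes allow
  expect_error(scene_config(groove_depth_frac = 0.48),
               "too large")
  expect_error(scene_config(groove_depth_frac = 0.01), "too small")
})

test_that("scene ground truth matches the analytic construction exactly", {
  cfg <- test_config(seed = 5, mtoc_offset = 0.5)
  sc <- make_scene(cfg)

  # implied polarity index equals the configured offset
  u <- (sc$bead_cm - sc$cell_cm)
  implied <- sum((sc$mtoc - sc$cell_cm) * u) / sum(u * u)
  expect_equal(implied, 0.5, tolerance = 1e-9)

  # depth point to apex baseline distance = frac * diameter
  h <- synmorph:::point_line_distance(sc$depth_point, sc$lobe_apices[[1]],
                                      sc$lobe_apices[[2]])
  expect_equal(h / (2 * cfg$cell_radius), cfg$groove_depth_frac,
               tolerance = 1e-9)

  # apices lie on the surface of the frontal lobes, outside the others
  geom <- sc$geom
  for (ap in sc$lobe_apices) {
    q <- as.numeric(t(sc$rotation) %*% (ap - sc$cell_cm))
    d <- sqrt(colSums((t(geom$lobe_centers) - q)^2))
    expect_equal(min(abs(d - geom$lobe_radii)), 0, tolerance = 1e-9)
    expect_true(all(d >= geom$lobe_radii - 1e-9))
  }

  # groove CM inside the cell, outside every lobe
  expect_lt(synmorph:::vnorm(sc$groove_cm - sc$cell_cm), cfg$cell_radius)
  qg <- as.numeric(t(sc$rotation) %*% (sc$groove_cm - sc$cell_cm))
  expect_false(synmorph:::inside_nucleus_canonical(qg[1], qg[2], qg[3], geom))
})

test_that("stored ground truth agrees with independent brute-force oracles", {
  cfg <- test_config(seed = 2)
  sc <- make_scene(cfg)
  geom <- sc$geom

  # groove half-width formula vs bisection on the membership test
  xs <- seq(geom$x_w + 0.05, geom$xA - 0.05, length.out = 25)
  expect_equal(synmorph:::groove_halfwidth(xs, 0, geom),
               oracle_groove_halfwidth(xs, 0, geom), tolerance = 1e-8)

  # nucleus volume vs independent 2D quadrature of the z chord
  expect_equal(sc$nucleus_volume_true, oracle_nucleus_volume(geom),
               tolerance = 1e-6)

  # mid-plane groove area and centroid vs grid sampling of the membership
  sect <- oracle_groove_section(geom)
  expect_equal(sc$groove_area_true, sect$area, tolerance = 1e-3)
  qg <- as.numeric(t(sc$rotation) %*% (sc$groove_cm - sc$cell_cm))
  expect_equal(qg[1], sect$cm_x, tolerance = 1e-3)
})

test_that("rendering is deterministic and conserves photons", {
  cfg <- test_config(seed = 9, noise = TRUE, on = c("nucleus", "bead"))
  sc <- make_scene(cfg)
  s1 <- render_stack(sc, cfg)
  s2 <- render_stack(sc, cfg)
  expect_identical(s1$intensities, s2$intensities)

  # PSF conserves total intensity for interior structures (noise off)
  cfg0 <- test_config(seed = 9, noise = FALSE, on = "nucleus")
  sc0 <- make_scene(cfg0)
  blurred <- render_stack(sc0, cfg0)
  cfg_nopsf <- cfg0
  cfg_nopsf$psf_sigma <- c(z = 0, y = 0, x = 0)
  sharp <- render_stack(sc0, cfg_nopsf)
  expect_equal(sum(channel_volume(blurred, "nucleus")),
               sum(channel_volume(sharp, "nucleus")), tolerance = 1e-3)

  # channels without structures stay identically zero
  expect_true(all(channel_volume(blurred, "lamp1") == 0))
})

test_that("Poisson noise has variance close to its mean", {
  cfg <- test_config(seed = 4, on = "bead")
  cfg$noise <- list(poisson_scale = 1, gaussian_sd = 0)
  cfg$psf_sigma <- c(z = 0, y = 0, x = 0)
  sc <- make_scene(cfg)
  st <- render_stack(sc, cfg)
  v <- channel_volume(st, "bead")
  g <- synmorph:::voxel_grid(dim(v), st$voxel_size)
  interior <- (g$X - sc$bead_cm[1])^2 + (g$Y - sc$bead_cm[2])^2 +
    (g$Z - sc$bead_cm[3])^2 <= (cfg$bead_radius - 0.4)^2
  expect_gt(sum(interior), 200)
  m <- mean(v[interior]); s2 <- var(v[interior])
  expect_lt(abs(s2 / m - 1), 0.05)
  expect_lt(abs(m / 500 - 1), 0.05)
})

test_that("antigen extraction time courses scale the bead OVA signal", {
  cfg <- test_config(seed = 3, on = c("ova", "bead"))
  tc <- make_timecourse(cfg, times = c(0, 30), extraction_fracs = c(0, 0.5))
  s0 <- sum(channel_volume(tc[[1]]$stack, "ova"))
  s1 <- sum(channel_volume(tc[[2]]$stack, "ova"))
  expect_equal(s1 / s0, 0.5, tolerance = 1e-6)

  tc3 <- make_timecourse(cfg, times = c(0, 1, 2),
                         extraction_fracs = c(0, 0, 0))
  sums <- vapply(tc3, function(t) sum(channel_volume(t$stack, "ova")), 0)
  expect_equal(sums[1], sums[2])
  expect_equal(sums[2], sums[3])

  expect_error(make_timecourse(cfg, c(0, 1), c(0.5, 0.2)), "monotone")
})

test_that("lysosome placement respects the configured mode", {
  for (mode in c("perinuclear", "synaptic_central", "synaptic_dispersed")) {
    cfg <- test_config(seed = 8, lysosome_mode = mode, lysosome_count = 10)
    sc <- make_scene(cfg)
    expect_equal(nrow(sc$lysosome_centers), 10)
    d_cell <- sqrt(rowSums((sc$lysosome_centers -
      matrix(sc$cell_cm, 10, 3, byrow = TRUE))^2))
    expect_true(all(d_cell < cfg$cell_radius))
    if (mode == "synaptic_central") {
      contact <- sc$cell_cm + cfg$cell_radius *
        (sc$bead_cm - sc$cell_cm) / synmorph:::vnorm(sc$bead_cm - sc$cell_cm)
      d_syn <- sqrt(rowSums((sc$lysosome_centers -
        matrix(contact, 10, 3, byrow = TRUE))^2))
      expect_true(all(d_syn < 2.01))
    }
  }
})
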