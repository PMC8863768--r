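# Synthetic confocal scenes of B cells with exact ground truth.
#
# Canonical frame: the cell centre sits at the origin and the principal
# nuclear groove opens toward +x. The nucleus is a union of 3-4 spherical
# lobes arranged on a ring in the xy plane, minus a dihedral wedge (edge
# parallel to z at x = x_w, half-angle groove_half_angle) that carves the
# principal groove between the two frontal lobes. The two frontal lobes
# share a radius and a common x centre, so the convex hull closes the
# groove mouth with the vertical tangent plane x = x_apex and the lobe
# apices are exactly the two tangency points (x_apex, +/-w, 0); the groove
# depth h = x_apex - x_w is therefore set exactly by groove_depth_frac.
# The scene is then rotated (bead mode: about z; dish mode: lobe-rotation
# parametrization, see rot_dish()) and translated into the stack.

DEFAULT_AMPLITUDES <- setNames(rep(500, 8), CHANNEL_ROLES)

#' Configuration of a synthetic B-cell scene
#'
#' All lengths in micrometres, angles in degrees. Defaults reproduce a
#' confocal acquisition of a mouse B lymphocyte (cell diameter 10 um,
#' 3-lobed nucleus, 3-um antigen-coated bead, 0.2 x 0.07 x 0.07 um voxels).
#'
#' @param cell_radius cell radius (um).
#' @param nucleus_lobe_count number of nuclear lobes, 3 or 4.
#' @param lobe_radii radii of the lobes (um), one per lobe; the first two
#'   are the groove-bounding frontal lobes and must be equal.
#' @param groove_half_angle half-angle of the wedge that carves the
#'   principal groove (degrees); controls the angular width of the groove.
#' @param groove_orientation bead mode: angle between the groove opening and
#'   the cell-to-bead axis. Dish mode: lobe-rotation angle from the
#'   synaptic-plane normal (0 = groove fully facing the synapse).
#' @param groove_depth_frac target groove depth h normalised by the cell
#'   diameter, in `[0, 1]` (feasible sub-range depends on the lobe geometry
#'   and is validated).
#' @param bead_present logical; render a 3-um antigen-coated bead.
#' @param bead_radius bead radius (um); default 1.5 (3-um latex bead).
#' @param bead_center optional bead centre (x, y, z) um; default places the
#'   bead in contact with the cell along the synapse axis.
#' @param mtoc_offset intended MTOC polarity index in `[-1, 1]`: the MTOC is
#'   placed on the cell-to-bead (or cell-to-synapse) axis at this signed
#'   fraction of the axis length.
#' @param lysosome_count number of lysosome puncta.
#' @param lysosome_mode one of `"perinuclear"`, `"synaptic_central"`,
#'   `"synaptic_dispersed"`.
#' @param channel_amplitudes named photon counts per structure voxel for
#'   channels `nucleus, actin, tubulin, lamp1, ova, exo70, bcr, bead`;
#'   channels with amplitude 0 are rendered empty.
#' @param psf_sigma Gaussian PSF sigma per axis, named `c(z=,y=,x=)` um;
#'   0 disables blurring along that axis.
#' @param noise list with `poisson_scale` (0 disables shot noise) and
#'   `gaussian_sd` (additive read noise, counts).
#' @param voxel_size voxel pitch `c(z=,y=,x=)` um.
#' @param stack_shape stack size in voxels `c(z=,y=,x=)`.
#' @param mode `"bead"` (bead conjugate) or `"dish"` (coverslip synapse;
#'   synaptic plane at z = 0 side of the stack).
#' @param scene_rotation extra rigid rotation of the whole scene about the
#'   z axis (degrees); used for equivariance checks.
#' @param cell_center optional cell centre (x, y, z) um.
#' @param rng_seed integer seed controlling lysosome placement and noise.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(cell_radius = 5,
                         nucleus_lobe_count = 3,
                         lobe_radii = NULL,
                         groove_half_angle = 15,
                         groove_orientation = 0,
                         groove_depth_frac = 0.25,
                         bead_present = TRUE,
                         bead_radius = 1.5,
                         bead_center = NULL,
                         mtoc_offset = 0.6,
                         lysosome_count = 12,
                         lysosome_mode = c("perinuclear", "synaptic_central",
                                           "synaptic_dispersed"),
                         channel_amplitudes = DEFAULT_AMPLITUDES,
                         psf_sigma = c(z = 0.25, y = 0.1, x = 0.1),
                         noise = list(poisson_scale = 1, gaussian_sd = 5),
                         voxel_size = c(z = 0.2, y = 0.07, x = 0.07),
                         stack_shape = c(z = 60, y = 186, x = 229),
                         mode = c("bead", "dish"),
                         scene_rotation = 0,
                         cell_center = NULL,
                         rng_seed = 1) {
  mode <- match.arg(mode)
  lysosome_mode <- match.arg(lysosome_mode)
  # YAML configs deliver named lists; coerce the numeric vectors
  zyx <- function(v) {
    v <- unlist(v)
    if (!is.null(names(v)) && all(c("z", "y", "x") %in% names(v)))
      v <- v[c("z", "y", "x")]
    v
  }
  voxel_size <- zyx(voxel_size)
  stack_shape <- zyx(stack_shape)
  psf_sigma <- zyx(psf_sigma)
  if (is.list(channel_amplitudes)) channel_amplitudes <- unlist(channel_amplitudes)
  if (!is.null(bead_center)) bead_center <- unlist(bead_center)
  if (!is.null(cell_center)) cell_center <- unlist(cell_center)
  if (is.null(lobe_radii)) {
    lobe_radii <- switch(as.character(nucleus_lobe_count),
                         "3" = c(2, 2, 3.2) * cell_radius / 5,
                         "4" = c(2, 2, 2.6, 2.6) * cell_radius / 5,
                         stop("nucleus_lobe_count must be 3 or 4"))
  }
  amp <- DEFAULT_AMPLITUDES
  if (!is.null(channel_amplitudes)) {
    if (is.null(names(channel_amplitudes)) ||
        !all(names(channel_amplitudes) %in% CHANNEL_ROLES))
      stop("channel_amplitudes must be named with channel roles: ",
           paste(CHANNEL_ROLES, collapse = ", "))
    amp[names(channel_amplitudes)] <- channel_amplitudes
  }
  cfg <- structure(list(
    cell_radius = cell_radius,
    nucleus_lobe_count = as.integer(nucleus_lobe_count),
    lobe_radii = lobe_radii,
    groove_half_angle = groove_half_angle,
    groove_orientation = groove_orientation,
    groove_depth_frac = groove_depth_frac,
    bead_present = isTRUE(bead_present),
    bead_radius = bead_radius,
    bead_center = bead_center,
    mtoc_offset = mtoc_offset,
    lysosome_count = as.integer(lysosome_count),
    lysosome_mode = lysosome_mode,
    channel_amplitudes = amp,
    psf_sigma = psf_sigma,
    noise = noise,
    voxel_size = voxel_size,
    stack_shape = as.integer(stack_shape),
    mode = mode,
    scene_rotation = scene_rotation,
    cell_center = cell_center,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  assert_pos(cfg$cell_radius, "cell_radius")
  assert_pos(cfg$lobe_radii, "lobe_radii")
  assert_pos(cfg$bead_radius, "bead_radius")
  assert_pos(cfg$voxel_size, "voxel_size")
  assert_pos(cfg$stack_shape, "stack_shape")
  assert_nonneg(cfg$psf_sigma, "psf_sigma")
  assert_nonneg(cfg$channel_amplitudes, "channel_amplitudes")
  assert_nonneg(cfg$noise$poisson_scale, "noise$poisson_scale")
  assert_nonneg(cfg$noise$gaussian_sd, "noise$gaussian_sd")
  assert_in(cfg$groove_depth_frac, 0, 1, "groove_depth_frac")
  assert_in(cfg$mtoc_offset, -1, 1, "mtoc_offset")
  assert_in(cfg$groove_half_angle, 1, 45, "groove_half_angle")
  if (!cfg$nucleus_lobe_count %in% c(3L, 4L))
    stop("nucleus_lobe_count must be 3 or 4")
  if (length(cfg$lobe_radii) != cfg$nucleus_lobe_count)
    stop("lobe_radii must have one entry per lobe")
  if (abs(cfg$lobe_radii[1] - cfg$lobe_radii[2]) > 1e-9)
    stop("the two groove-bounding lobes (lobe_radii[1:2]) must share a radius")
  geom <- canonical_geometry(cfg)   # performs geometric feasibility checks
  fit <- max(sqrt(rowSums(geom$lobe_centers^2)) + geom$lobe_radii)
  if (fit > cfg$cell_radius + 1e-9)
    stop(sprintf(paste0("invalid geometry: nucleus larger than cell ",
                        "(lobe reach %.2f um exceeds cell radius %.2f um)"),
                 fit, cfg$cell_radius))
  invisible(cfg)
}

# Canonical-frame nucleus geometry: lobe centres/radii and groove wedge.
canonical_geometry <- function(cfg) {
  R <- cfg$cell_radius
  d <- 0.48 * R                       # lobe ring radius
  phi <- 40 * pi / 180                # angular position of the frontal lobes
  rl <- cfg$lobe_radii[1]
  xc <- d * cos(phi)
  w <- d * sin(phi)
  if (w >= rl)
    stop("invalid geometry: groove mouth wider than the frontal lobes")
  k <- cfg$nucleus_lobe_count
  centers <- rbind(c(xc, w, 0), c(xc, -w, 0))
  if (k == 3L) {
    centers <- rbind(centers, c(-0.32 * R, 0, 0))
  } else {
    psi <- 140 * pi / 180
    centers <- rbind(centers,
                     c(d * cos(psi), d * sin(psi), 0),
                     c(d * cos(psi), -d * sin(psi), 0))
  }
  xA <- xc + rl
  h <- cfg$groove_depth_frac * 2 * R
  h_nat <- rl - sqrt(rl^2 - w^2)
  if (h < h_nat - 1e-9)
    stop(sprintf(paste0("groove_depth_frac too small for the lobe geometry: ",
                        "the notch between the frontal lobes is already ",
                        "%.3f of the diameter"), h_nat / (2 * R)))
  x_w <- xA - h
  if (x_w <= xc - rl + 0.1)
    stop("groove_depth_frac too large for the lobe geometry: the wedge would cut through the frontal lobes")
  tanb <- tan(cfg$groove_half_angle * pi / 180)
  if (h * tanb > 0.95 * w)
    stop("groove_half_angle too wide: the wedge would truncate the lobe apices")
  w_min <- min(0.25, 0.5 * w)   # groove floor half-width (um): the slot
                                # bottom is optically resolvable, not a cusp
  list(R = R, lobe_centers = centers, lobe_radii = cfg$lobe_radii,
       xc = xc, w = w, rl = rl, xA = xA, x_w = x_w, h = h, tanb = tanb,
       w_min = w_min)
}

# ---- exact quadrature for the analytic nucleus -------------------------

# Chord length of the nucleus along z at fixed (x, y), vectorised over y.
# Every lobe is centred in the plane z = 0, so the per-lobe z chords
# [-s_i, s_i] are nested and the union chord is simply 2 * max_i s_i; the
# wedge (independent of z) removes the whole chord where |y| < t(x).
nucleus_z_chord <- function(x, y, geom) {
  s2max <- rep(0, length(y))
  for (i in seq_len(nrow(geom$lobe_centers))) {
    ci <- geom$lobe_centers[i, ]
    s2 <- geom$lobe_radii[i]^2 - (x - ci[1])^2 - (y - ci[2])^2
    s2max <- pmax(s2max, s2)
  }
  len <- 2 * sqrt(pmax(0, s2max))
  t <- if (x > geom$x_w) max(geom$w_min, (x - geom$x_w) * geom$tanb) else 0
  len[abs(y) < t] <- 0
  len
}

# Cross-section area of the nucleus in the (y, z) plane at position x,
# integrating the exact z chord piecewise-analytically over y. Within a
# sub-interval delimited by lobe support edges and pairwise switch points
# the maximising lobe is constant, so each piece has the closed-form
# circular-segment antiderivative F(y).
nucleus_yz_area <- function(x, geom) {
  cy <- geom$lobe_centers[, 2]
  a <- geom$lobe_radii^2 - (x - geom$lobe_centers[, 1])^2
  sup <- which(a > 0)
  if (!length(sup)) return(0)
  t <- if (x > geom$x_w) max(geom$w_min, (x - geom$x_w) * geom$tanb) else 0
  ymax <- max(cy[sup] + sqrt(a[sup]))
  if (ymax <= t) return(0)
  # breakpoints: wedge edge, lobe support edges, pairwise switch points
  bp <- c(t, ymax)
  for (i in sup) bp <- c(bp, cy[i] - sqrt(a[i]), cy[i] + sqrt(a[i]))
  if (length(sup) > 1) {
    for (ii in seq_along(sup)) for (jj in seq_along(sup)) {
      if (jj <= ii) next
      i <- sup[ii]; j <- sup[jj]
      if (abs(cy[i] - cy[j]) > 1e-12)
        bp <- c(bp, (a[j] - a[i] + cy[i]^2 - cy[j]^2) / (2 * (cy[i] - cy[j])))
    }
  }
  bp <- sort(unique(pmin(pmax(bp, t), ymax)))
  Fseg <- function(i, y) {
    u <- pmin(pmax(y - cy[i], -sqrt(a[i])), sqrt(a[i]))
    u * sqrt(pmax(0, a[i] - u^2)) + a[i] * asin(u / sqrt(a[i]))
  }
  acc <- 0
  for (k in seq_len(length(bp) - 1L)) {
    y1 <- bp[k]; y2 <- bp[k + 1L]
    if (y2 - y1 < 1e-14) next
    ym <- (y1 + y2) / 2
    s2 <- a[sup] - (ym - cy[sup])^2
    if (max(s2) <= 0) next
    i <- sup[which.max(s2)]
    acc <- acc + (Fseg(i, y2) - Fseg(i, y1))
  }
  2 * acc   # symmetric in y; chord length is 2 * s
}

# Nucleus volume: 1D adaptive quadrature of the exact cross-section area.
nucleus_volume_quadrature <- function(geom) {
  x1 <- min(geom$lobe_centers[, 1] - geom$lobe_radii)
  x2 <- max(geom$lobe_centers[, 1] + geom$lobe_radii)
  integrate(function(x) vapply(x, nucleus_yz_area, 0, geom = geom),
            x1, x2, subdivisions = 2000L, rel.tol = 1e-10,
            stop.on.error = FALSE)$value
}

# Half-width in y of the principal groove (hull deficit) at (x, z);
# vectorised over x. The groove is bounded above by the first nuclear
# material met when walking away from the groove mid-plane y = 0.
groove_halfwidth <- function(x, z, geom) {
  t <- ifelse(x > geom$x_w, pmax(geom$w_min, (x - geom$x_w) * geom$tanb), 0)
  yup <- rep(Inf, length(x))
  for (i in seq_len(nrow(geom$lobe_centers))) {
    ci <- geom$lobe_centers[i, ]; ri <- geom$lobe_radii[i]
    s2 <- ri^2 - (z - ci[3])^2 - (x - ci[1])^2
    ok <- s2 > 0
    s <- sqrt(pmax(s2, 0))
    cand <- pmax(t, ci[2] - s)
    valid <- ok & (ci[2] + s >= cand)
    yup[valid] <- pmin(yup[valid], cand[valid])
  }
  yup[!is.finite(yup)] <- 0
  pmax(yup, 0)
}

# Area of the principal-groove cross-section in the plane at height z.
groove_slice_area <- function(z, geom) {
  s2 <- geom$rl^2 - z^2
  if (s2 <= 0) return(0)
  xA_z <- geom$xc + sqrt(s2)
  if (xA_z <= geom$x_w) return(0)
  2 * integrate(function(x) groove_halfwidth(x, z, geom),
                geom$x_w, xA_z, subdivisions = 400L,
                rel.tol = 1e-9, stop.on.error = FALSE)$value
}

# Centroid (x only; y = z = 0 by symmetry) of the mid-plane groove section.
groove_centroid_x <- function(geom) {
  den <- integrate(function(x) groove_halfwidth(x, 0, geom),
                   geom$x_w, geom$xA, subdivisions = 400L,
                   rel.tol = 1e-10, stop.on.error = FALSE)$value
  num <- integrate(function(x) x * groove_halfwidth(x, 0, geom),
                   geom$x_w, geom$xA, subdivisions = 400L,
                   rel.tol = 1e-10, stop.on.error = FALSE)$value
  num / den
}

# The quadrature ground truths depend only on the canonical lobe/wedge
# geometry, which is shared by every scene of a parameter grid; memoise.
.quad_cache <- new.env(parent = emptyenv())

geometry_quadratures <- function(geom) {
  key <- paste(signif(c(geom$lobe_centers, geom$lobe_radii, geom$x_w,
                        geom$tanb, geom$w_min), 12), collapse = "|")
  hit <- .quad_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- list(volume = nucleus_volume_quadrature(geom),
              area0 = groove_slice_area(0, geom),
              cm_x = groove_centroid_x(geom))
  .quad_cache[[key]] <- res
  res
}

# canonical-frame membership test for the nucleus, vectorised over points
inside_nucleus_canonical <- function(px, py, pz, geom) {
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nrow(geom$lobe_centers))) {
    ci <- geom$lobe_centers[i, ]
    inside <- inside |
      ((px - ci[1])^2 + (py - ci[2])^2 + (pz - ci[3])^2 <= geom$lobe_radii[i]^2)
  }
  wedge <- (px > geom$x_w) &
    (abs(py) < pmax(geom$w_min, (px - geom$x_w) * geom$tanb))
  inside & !wedge
}

# ---- scene assembly ----------------------------------------------------

#' Build the analytic ground-truth scene for a configuration
#'
#' Deterministic given `rng_seed`. Returns the centres of mass of cell,
#' bead and groove, the lobe apices bounding the groove opening, the MTOC
#' and lysosome positions, and exact nuclear volume / groove depth / groove
#' area obtained from the analytic geometry (volume and groove area by
#' adaptive quadrature of exact cross-sections, everything else in closed
#' form).
#'
#' @param config a [scene_config()].
#' @return object of class `cell_scene`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  geom <- canonical_geometry(config)
  R <- config$cell_radius
  vox <- config$voxel_size
  ext <- config$stack_shape * vox      # (z, y, x) extents, um

  center <- config$cell_center
  if (is.null(center)) {
    # bead mode: leave room for the bead on +x and for a fully
    # anti-polarized MTOC (mirrored bead distance) on -x
    center <- if (config$mode == "bead") {
      c(ext[3] - (R + 2 * config$bead_radius + 1.2), ext[2] / 2, ext[1] / 2)
    } else {
      c(ext[3] / 2, ext[2] / 2, R + 0.2)
    }
  }

  Rsc <- rot_z(config$scene_rotation)
  if (config$mode == "bead") {
    axis_world <- as.numeric(Rsc %*% c(1, 0, 0))
    Rn <- Rsc %*% rot_z(config$groove_orientation)
    synapse_z <- NA_real_
  } else {
    Rn <- Rsc %*% rot_dish(config$groove_orientation)
    synapse_z <- center[3] - R
    axis_world <- unit_vec(c(center[1], center[2], synapse_z) - center)
  }

  bead_cm <- NULL
  if (config$bead_present) {
    bead_cm <- config$bead_center %||%
      (center + (R + config$bead_radius) * axis_world)
    gap <- vnorm(bead_cm - center) - (R + config$bead_radius)
    if (gap < -0.5)
      stop("bead overlaps the cell interior beyond the contact cap (0.5 um)")
  }

  # polarity axis: cell -> bead (bead mode) or cell -> synapse plane foot
  pol_target <- if (!is.null(bead_cm)) bead_cm else
    c(center[1], center[2], synapse_z)
  mtoc <- center + config$mtoc_offset * (pol_target - center)

  lyso <- sample_lysosomes(config, geom, Rn, center, bead_cm, pol_target)

  apices <- list(center + as.numeric(Rn %*% c(geom$xA, geom$w, 0)),
                 center + as.numeric(Rn %*% c(geom$xA, -geom$w, 0)))
  depth_point <- center + as.numeric(Rn %*% c(geom$x_w, 0, 0))
  quad <- geometry_quadratures(geom)
  groove_cm <- center + as.numeric(Rn %*% c(quad$cm_x, 0, 0))

  structure(list(
    cell_cm = center,
    bead_cm = bead_cm,
    groove_cm = groove_cm,
    lobe_apices = apices,
    depth_point = depth_point,
    mtoc = mtoc,
    lysosome_centers = lyso,
    nucleus_volume_true = quad$volume,
    groove_depth_true = config$groove_depth_frac,
    groove_area_true = quad$area0,
    bead_signal_per_time = config$channel_amplitudes[["ova"]],
    synapse_z = synapse_z,
    groove_axis = as.numeric(Rn %*% c(1, 0, 0)),
    rotation = Rn,
    geom = geom,
    mode = config$mode,
    config = config
  ), class = "cell_scene")
}

sample_lysosomes <- function(config, geom, Rn, center, bead_cm, pol_target) {
  n <- config$lysosome_count
  if (n == 0) return(matrix(numeric(0), 0, 3))
  R <- config$cell_radius
  bead_c <- if (!is.null(bead_cm)) as.numeric(t(Rn) %*% (bead_cm - center)) else NULL
  # synapse reference: the membrane contact point on the cell->target axis
  syn_axis <- as.numeric(t(Rn) %*% (pol_target - center))
  syn_dir <- unit_vec(syn_axis)
  syn_c <- syn_dir * min(R, vnorm(syn_axis))
  with_seed(config$rng_seed, {
    acc <- matrix(numeric(0), 0, 3)
    for (it in 1:200) {
      m <- 512
      p <- cbind(runif(m, -R, R), runif(m, -R, R), runif(m, -R, R))
      r <- sqrt(rowSums(p^2))
      keep <- r < R - 0.4
      keep <- keep & !inside_nucleus_canonical(p[, 1], p[, 2], p[, 3], geom)
      if (!is.null(bead_c))
        keep <- keep & (sqrt(rowSums((p - rep(bead_c, each = m))^2)) >
                          config$bead_radius + 0.3)
      sd_nuc <- apply(p, 1, function(q) {
        min(sqrt(colSums((t(geom$lobe_centers) - q)^2)) - geom$lobe_radii)
      })
      keep <- keep & switch(config$lysosome_mode,
        perinuclear = sd_nuc < 0.8,
        synaptic_central = sqrt(rowSums((p - rep(syn_c, each = m))^2)) < 2.0,
        synaptic_dispersed = {
          ax <- as.numeric(p %*% syn_dir)
          lat <- sqrt(pmax(0, rowSums(p^2) - ax^2))
          (abs(ax - vnorm(syn_c)) < 2.0) & (lat < 4.0)
        })
      acc <- rbind(acc, p[keep, , drop = FALSE])
      if (nrow(acc) >= n) break
    }
    if (nrow(acc) < n)
      stop("could not place lysosomes under mode '", config$lysosome_mode, "'")
    pts <- acc[seq_len(n), , drop = FALSE]
    t(apply(pts, 1, function(q) center + as.numeric(Rn %*% q)))
  })
}

#' Fraction of lysosome ground-truth intensity near the bead
#'
#' Fraction of puncta centres within `radius_um` of the bead centre of
#' mass; with equal-amplitude puncta this is the ground truth of
#' [lamp_ring_fraction()].
#' @param scene a `cell_scene`.
#' @param radius_um ring radius (um), default 3.5.
#' @export
scene_ring_fraction <- function(scene, radius_um = 3.5) {
  if (is.null(scene$bead_cm)) stop("scene has no bead")
  p <- scene$lysosome_centers
  if (nrow(p) == 0) return(NA_real_)
  d <- sqrt(rowSums((p - matrix(scene$bead_cm, nrow(p), 3, byrow = TRUE))^2))
  mean(d <= radius_um)
}

# ---- rendering ---------------------------------------------------------

# Normalised 1D Gaussian kernel; NULL if sigma_px is negligible.
gauss_kernel <- function(sigma_px) {
  if (sigma_px < 1e-3) return(NULL)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# Separable Gaussian blur of a (z, y, x) volume, sigma in voxels per axis.
blur3d <- function(vol, sigma_px) {
  dm <- dim(vol)
  conv_axis <- function(v, k, axis) {
    if (is.null(k)) return(v)
    n <- dim(v)[axis]
    r <- (length(k) - 1L) / 2L
    B <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i <- (j - r):(j + r)
      ok <- i >= 1 & i <= n
      B[i[ok], j] <- k[ok]
    }
    if (axis == 1L) {
      array(B %*% matrix(v, dim(v)[1]), dim(v))
    } else if (axis == 3L) {
      array(matrix(v, prod(dim(v)[1:2])) %*% t(B), dim(v))
    } else {
      vp <- aperm(v, c(2, 1, 3))
      vp <- array(B %*% matrix(vp, dim(vp)[1]), dim(vp))
      aperm(vp, c(2, 1, 3))
    }
  }
  vol <- conv_axis(vol, gauss_kernel(sigma_px[1]), 1L)
  vol <- conv_axis(vol, gauss_kernel(sigma_px[2]), 2L)
  conv_axis(vol, gauss_kernel(sigma_px[3]), 3L)
}

sphere_indicator <- function(g, center, radius) {
  (g$X - center[1])^2 + (g$Y - center[2])^2 + (g$Z - center[3])^2 <= radius^2
}

shell_indicator <- function(g, center, r_in, r_out) {
  r2 <- (g$X - center[1])^2 + (g$Y - center[2])^2 + (g$Z - center[3])^2
  r2 <= r_out^2 & r2 > r_in^2
}

check_contained <- function(name, lo, hi, ext) {
  if (any(lo < 0) || any(hi > ext))
    stop(sprintf("stack_shape too small: structure '%s' extends beyond the image",
                 name))
}

#' Render a scene into a multi-channel image stack
#'
#' Voxelises each structure into its channel (photons per structure voxel
#' from `channel_amplitudes`), convolves with a separable Gaussian PSF and
#' applies Poisson shot noise followed by additive Gaussian read noise.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param scene a `cell_scene` from [make_scene()].
#' @param config the [scene_config()] the scene was built from.
#' @param extraction_frac fraction of bead-bound antigen (OVA channel)
#'   already extracted; scales the OVA amplitude by `1 - extraction_frac`.
#' @return an `image_stack`.
#' @export
render_stack <- function(scene, config = scene$config, extraction_frac = 0) {
  stopifnot(inherits(scene, "cell_scene"))
  assert_in(extraction_frac, 0, 1, "extraction_frac")
  vox <- config$voxel_size
  shp <- config$stack_shape
  ext <- rev(shp * vox)                       # (x, y, z) extents
  R <- config$cell_radius
  ctr <- scene$cell_cm

  check_contained("cell", ctr - R, ctr + R, ext)
  if (!is.null(scene$bead_cm))
    check_contained("bead", scene$bead_cm - config$bead_radius,
                    scene$bead_cm + config$bead_radius, ext)
  check_contained("mtoc", scene$mtoc - 0.3, scene$mtoc + 0.3, ext)

  g <- voxel_grid(shp, vox)
  # canonical coordinates of every voxel centre
  Rt <- t(scene$rotation)
  qx <- Rt[1, 1] * (g$X - ctr[1]) + Rt[1, 2] * (g$Y - ctr[2]) + Rt[1, 3] * (g$Z - ctr[3])
  qy <- Rt[2, 1] * (g$X - ctr[1]) + Rt[2, 2] * (g$Y - ctr[2]) + Rt[2, 3] * (g$Z - ctr[3])
  qz <- Rt[3, 1] * (g$X - ctr[1]) + Rt[3, 2] * (g$Y - ctr[2]) + Rt[3, 3] * (g$Z - ctr[3])

  amp <- config$channel_amplitudes
  vols <- list()
  zero <- array(0, dim = c(shp[1], shp[2], shp[3]))

  build <- function(role, ind_fun) {
    if (amp[[role]] <= 0) return(zero)
    amp[[role]] * ind_fun()
  }
  geom <- scene$geom
  vols$nucleus <- build("nucleus", function()
    array(as.numeric(inside_nucleus_canonical(qx, qy, qz, geom)), dim(qx)))
  vols$actin <- build("actin", function() shell_indicator(g, ctr, R - 0.35, R))
  vols$tubulin <- build("tubulin", function() sphere_indicator(g, scene$mtoc, 0.25))
  vols$lamp1 <- build("lamp1", function() {
    acc <- zero
    for (i in seq_len(nrow(scene$lysosome_centers)))
      acc <- acc + sphere_indicator(g, scene$lysosome_centers[i, ], 0.25)
    pmin(acc, 1)
  })
  vols$ova <- build("ova", function() {
    if (is.null(scene$bead_cm)) return(zero)
    (1 - extraction_frac) *
      shell_indicator(g, scene$bead_cm, config$bead_radius - 0.25,
                      config$bead_radius)
  })
  vols$exo70 <- build("exo70", function() sphere_indicator(g, scene$mtoc, 0.4))
  vols$bcr <- build("bcr", function() shell_indicator(g, ctr, R - 0.2, R))
  vols$bead <- build("bead", function() {
    if (is.null(scene$bead_cm)) return(zero)
    sphere_indicator(g, scene$bead_cm, config$bead_radius)
  })

  sigma_px <- config$psf_sigma / vox
  arr <- array(0, dim = c(length(CHANNEL_ROLES), shp[1], shp[2], shp[3]))
  with_seed(config$rng_seed + 1L, {
    for (i in seq_along(CHANNEL_ROLES)) {
      v <- vols[[CHANNEL_ROLES[i]]]
      if (any(v > 0)) {
        v <- blur3d(v, sigma_px)
        ps <- config$noise$poisson_scale
        gs <- config$noise$gaussian_sd
        if (ps > 0) v <- array(rpois(length(v), v * ps) / ps, dim(v))
        if (gs > 0) v <- v + array(rnorm(length(v), 0, gs), dim(v))
        v[v < 0] <- 0
      }
      arr[i, , , ] <- v
    }
  })
  image_stack(arr, voxel_size = vox, channel_roles = CHANNEL_ROLES,
              metadata = list(mode = config$mode,
                              synapse_z = scene$synapse_z,
                              extraction_frac = extraction_frac))
}

#' Simulate an antigen-extraction time course
#'
#' Renders the same scene at successive incubation times with the
#' bead-bound OVA amplitude scaled by `1 - extraction_fracs[t]`; noise is
#' drawn independently per time point (seeded, deterministic).
#'
#' @param config a [scene_config()].
#' @param times time labels (minutes), same length as `extraction_fracs`.
#' @param extraction_fracs per-time extracted fraction in `[0, 1]`,
#'   non-decreasing (extraction is monotone in this model).
#' @return list of `list(time, scene, stack)`, one per time point.
#' @export
make_timecourse <- function(config, times, extraction_fracs) {
  if (length(times) != length(extraction_fracs))
    stop("times and extraction_fracs must have the same length")
  assert_in(extraction_fracs, 0, 1, "extraction_fracs")
  if (any(diff(extraction_fracs) < -1e-12))
    stop("extraction_fracs must be non-decreasing: extraction is monotone in this model")
  scene <- make_scene(config)
  a0 <- config$channel_amplitudes[["ova"]]
  scene$bead_signal_per_time <- a0 * (1 - extraction_fracs)
  lapply(seq_along(times), function(i) {
    cfg_t <- config
    cfg_t$rng_seed <- config$rng_seed + 1000L * (i - 1L)
    sc <- scene
    sc$config <- cfg_t
    list(time = times[i], scene = sc,
         stack = render_stack(sc, cfg_t, extraction_frac = extraction_fracs[i]))
  })
}
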