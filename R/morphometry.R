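# Quantitative measures of nuclear and organelle organisation at the
# immune synapse: orientation angles, polarity indexes, intensity rings,
# z and radial profiles, antigen extraction and surface staining.

#' Nuclear groove orientation relative to the bead axis
#'
#' Angle between the vector from the cell centre of mass (b) to the bead
#' centre of mass (a) and the vector from the cell centre to the nuclear
#' groove centre (c), in degrees.
#'
#' @param bead_cm,cell_cm,groove_cm points `(x, y, z)` in um.
#' @return angle in `[0, 180]`.
#' @export
groove_orientation_bead <- function(bead_cm, cell_cm, groove_cm) {
  angle_between_deg(bead_cm - cell_cm, groove_cm - cell_cm)
}

#' Classify a groove orientation angle
#'
#' Polarized on `[0, 45]`, Central on `(45, 135]`, Antipolarized on
#' `(135, 180]` with the default bins (closed lower bin, so the Polarized
#' supremum is exactly 45 degrees).
#'
#' @param angle_deg angle(s) in `[0, 180]`.
#' @param bin_edges increasing edges spanning `[0, 180]`; with the default
#'   4 edges the categories are named, otherwise `bin1..binN`.
#' @return character vector of categories.
#' @export
classify_orientation <- function(angle_deg, bin_edges = c(0, 45, 135, 180)) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0) || any(angle_deg > 180))
    stop("angle must lie in [0, 180]")
  labels <- if (length(bin_edges) == 4)
    c("Polarized", "Central", "Antipolarized")
  else paste0("bin", seq_len(length(bin_edges) - 1))
  as.character(cut(angle_deg, bin_edges, labels = labels,
                   include.lowest = TRUE, right = TRUE))
}

#' Groove orientation in the coverslip (dish) geometry
#'
#' Angle between the cell-to-groove vector and the perpendicular dropped
#' from the cell centre onto the synaptic plane `z = synapse_plane_z`;
#' 0 means the groove faces the synapse.
#'
#' @param cell_cm,groove_cm points `(x, y, z)` um.
#' @param synapse_plane_z z position of the synaptic plane (um).
#' @return angle in `[0, 180]`.
#' @export
groove_orientation_dish <- function(cell_cm, groove_cm, synapse_plane_z) {
  if (abs(cell_cm[3] - synapse_plane_z) < 1e-9)
    stop("cell centre lies on the synaptic plane")
  foot <- c(0, 0, synapse_plane_z - cell_cm[3])
  angle_between_deg(groove_cm - cell_cm, foot)
}

#' Rotation of the lobe baseline relative to the synaptic plane
#'
#' Angle between the line joining the two lobe apices and the synaptic
#' plane, folded to `[0, 90]`: 0 means the baseline is parallel to the
#' plane (fully rotated groove, lobes resting on the synapse), 90 means the
#' lobes are stacked perpendicular to it. The raw angle between the
#' baseline vector and the plane normal (in `[0, 180]`) is also returned.
#'
#' @param apices list of two apex points `(x, y, z)` um.
#' @param synapse_plane_z z position of the synaptic plane (unused in the
#'   angle itself; kept for interface symmetry).
#' @return list with `angle_deg` (folded, `[0, 90]`) and `raw_deg`.
#' @export
lobe_rotation <- function(apices, synapse_plane_z = 0) {
  b <- apices[[2]] - apices[[1]]
  if (vnorm(b) < 1e-9) stop("coincident apices")
  raw <- angle_between_deg(b, c(0, 0, 1))
  list(angle_deg = abs(90 - raw), raw_deg = raw)
}

#' Polarity index of a target relative to the cell-bead axis
#'
#' The target centre of mass is projected onto the axis from the cell
#' centre of mass (Cellmc) to the bead centre of mass (Beadmc); the index
#' is the signed ratio of the projected distance to the cell-bead
#' distance, negative when the projection falls on the anti-bead side, and
#' clamped to `[-1, 1]` (+1 fully polarized, -1 anti-polarized). The same
#' operation serves the MTOC (point target) and lysosomes
#' (intensity-weighted LAMP1 centre of mass).
#'
#' @param target_cm,cell_cm,bead_cm points `(x, y, z)` um.
#' @return object of class `polarity_result` with fields `index`,
#'   `cell_cm`, `bead_cm`, `target_cm` and `projection`.
#' @export
polarity_index <- function(target_cm, cell_cm, bead_cm) {
  axis <- bead_cm - cell_cm
  L <- vnorm(axis)
  if (L < 1e-9) stop("degenerate axis: cell and bead centres coincide")
  u <- axis / L
  s <- sum((target_cm - cell_cm) * u)
  structure(list(index = max(-1, min(1, s / L)),
                 cell_cm = cell_cm, bead_cm = bead_cm, target_cm = target_cm,
                 projection = cell_cm + s * u),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("polarity index: %+.3f\n", x$index))
  invisible(x)
}

#' Fraction of LAMP1 intensity in the ring around the bead
#'
#' LAMP1 intensity inside the sphere (default) or xy disc at the bead z
#' (`mode = "2d"`) of radius `ring_radius_um` around the bead centre,
#' normalised by the total cellular LAMP1 intensity.
#'
#' @param stack an `image_stack` with a `lamp1` channel.
#' @param bead_cm bead centre `(x, y, z)` um.
#' @param ring_radius_um ring radius, default 3.5.
#' @param mode `"3d"` sphere or `"2d"` disc at the bead z-slice.
#' @param cell_mask optional `mask3d` restricting the total intensity.
#' @param background flat background level subtracted before summation
#'   (see [channel_background()]).
#' @return fraction in `[0, 1]`, or `NA` when total intensity is zero.
#' @export
lamp_ring_fraction <- function(stack, bead_cm, ring_radius_um = 3.5,
                               mode = c("3d", "2d"), cell_mask = NULL,
                               background = 0) {
  mode <- match.arg(mode)
  v <- channel_volume(stack, "lamp1") - background
  if (!is.null(cell_mask)) v <- v * cell_mask$voxels
  tot <- sum(v)
  if (tot <= 0) { warning("zero total LAMP1 intensity"); return(NA_real_) }
  g <- voxel_grid(dim(v), stack$voxel_size)
  if (mode == "3d") {
    inside <- (g$X - bead_cm[1])^2 + (g$Y - bead_cm[2])^2 +
      (g$Z - bead_cm[3])^2 <= ring_radius_um^2
  } else {
    zi <- pmin(pmax(round(bead_cm[3] / stack$voxel_size[1] + 0.5), 1), dim(v)[1])
    inside <- array(FALSE, dim(v))
    inside[zi, , ] <- (g$X[zi, , ] - bead_cm[1])^2 +
      (g$Y[zi, , ] - bead_cm[2])^2 <= ring_radius_um^2
  }
  sum(v[inside]) / tot
}

#' Normalised z-distribution of a marker from the synapse
#'
#' Mean fluorescence intensity of the channel inside the cell at each of
#' `n_slices` slabs of thickness `step_um` starting at the synaptic plane,
#' each divided by the total over the analysed slabs and multiplied by 100
#' (so the values sum to 100 whenever signal exists).
#'
#' @param stack an `image_stack`.
#' @param role channel role (`"lamp1"`, `"bcr"`, ...).
#' @param synapse_z z of the synaptic plane (um).
#' @param n_slices number of slabs (default 10).
#' @param step_um slab thickness (default 0.2 um).
#' @param cell_mask optional `mask3d` defining "in the cell".
#' @param norm `"slices"` normalises over the analysed slabs;
#'   `"stack"` over the whole-channel total (values then sum to <= 100).
#' @param background flat background level subtracted before averaging.
#' @return numeric vector of `n_slices` percentages (NA when no signal).
#' @export
z_distribution <- function(stack, role, synapse_z, n_slices = 10,
                           step_um = 0.2, cell_mask = NULL,
                           norm = c("slices", "stack"), background = 0) {
  norm <- match.arg(norm)
  v <- channel_volume(stack, role) - background
  dz <- stack$voxel_size[1]
  zc <- axis_centers(dim(v)[1], dz)
  w <- if (!is.null(cell_mask)) cell_mask$voxels else array(TRUE, dim(v))
  mfi <- vapply(seq_len(n_slices), function(i) {
    zin <- zc >= synapse_z + (i - 1) * step_um & zc < synapse_z + i * step_um
    if (!any(zin)) return(NA_real_)
    sel <- w[zin, , , drop = FALSE]
    if (!any(sel)) return(NA_real_)
    vv <- v[zin, , , drop = FALSE]
    sum(vv[sel]) / sum(sel)
  }, 0)
  tot <- if (norm == "slices") sum(mfi, na.rm = TRUE) else sum(v)
  if (!is.finite(tot) || tot <= 0) {
    warning("no signal in the analysed z range")
    return(rep(NA_real_, n_slices))
  }
  100 * mfi / tot
}

#' Position of the largest lysosome cluster relative to the nucleus
#'
#' The perinuclear region is the shell within `margin_um` of the nucleus;
#' a cluster partially inside the nucleus or its perinuclear shell (one
#' voxel suffices) is "inside", otherwise "outside".
#'
#' @param lamp_mask `mask3d` of segmented LAMP1 signal.
#' @param nucleus_mask `mask3d` of the nucleus, same shape.
#' @param margin_um perinuclear margin (default 1 um).
#' @return `"inside"` or `"outside"` (`NA` for an empty LAMP mask).
#' @export
cluster_position <- function(lamp_mask, nucleus_mask, margin_um = 1) {
  if (!any(lamp_mask$voxels)) {
    warning("empty LAMP1 mask"); return(NA_character_)
  }
  regs <- connected_components(lamp_mask, connectivity = 26)
  cl <- regs$labels == regs$table$label[1]
  vs <- lamp_mask$voxel_size
  nuc <- nucleus_mask$voxels
  if (any(cl & nuc)) return("inside")
  # in-plane distance maps to the nucleus, per slice, combined with the
  # z offset to bound the 3D distance
  dm <- dim(nuc)
  dmap <- array(Inf, dm)
  for (z in seq_len(dm[1])) {
    sl <- nuc[z, , ]
    if (any(sl))
      dmap[z, , ] <- EBImage::distmap(matrix(as.numeric(!sl), dm[2], dm[3])) * vs[2]
  }
  idx <- which(cl)
  zi <- (idx - 1L) %% dm[1] + 1L
  kmax <- floor(margin_um / vs[1])
  for (k in -kmax:kmax) {
    zk <- zi + k
    ok <- zk >= 1 & zk <= dm[1]
    if (!any(ok)) next
    lim <- sqrt(margin_um^2 - (k * vs[1])^2)
    shifted <- idx[ok] + as.integer(k)
    if (any(dmap[shifted] <= lim)) return("inside")
  }
  "outside"
}

#' Radial intensity profile around a reference point
#'
#' Mean fluorescence intensity over xy discs of growing radius centred on
#' the reference point, in the z-slice containing it (the Exo70-around-
#' MTOC measure).
#'
#' @param stack an `image_stack`.
#' @param role channel role.
#' @param ref_point `(x, y, z)` um; must lie inside the stack.
#' @param r_max_um maximum radius (default 2 um).
#' @param dr_um radius step (default one xy pixel).
#' @return data.frame with `radius_um` and `mfi`.
#' @export
radial_profile <- function(stack, role, ref_point, r_max_um = 2,
                           dr_um = NULL) {
  v <- channel_volume(stack, role)
  vs <- stack$voxel_size
  ext <- rev(dim(v) * vs)
  if (any(ref_point < 0) || any(ref_point > ext))
    stop("reference point lies outside the image")
  dr_um <- dr_um %||% vs[3]
  zi <- pmin(pmax(ceiling(ref_point[3] / vs[1]), 1), dim(v)[1])
  sl <- v[zi, , ]
  yc <- axis_centers(dim(v)[2], vs[2]); xc <- axis_centers(dim(v)[3], vs[3])
  d2 <- outer((yc - ref_point[2])^2, (xc - ref_point[1])^2, `+`)
  radii <- seq(dr_um, r_max_um, by = dr_um)
  mfi <- vapply(radii, function(r) {
    sel <- d2 <= r^2
    if (!any(sel)) NA_real_ else mean(sl[sel])
  }, 0)
  data.frame(radius_um = radii, mfi = mfi)
}

#' Antigen extraction percentage over a bead time course
#'
#' For each time point, OVA fluorescence is summed over z (sum projection)
#' inside a fixed disc around the bead; extraction at time t is
#' `(1 - I(t) / mean I(0)) * 100`, clamped to `[0, 100]`.
#'
#' @param stacks list of `image_stack`s, the first being t = 0.
#' @param bead_cms bead centre per time point: one `(x, y, z)` point or a
#'   list of points.
#' @param area_radius_um radius of the fixed disc (default 2.5 um).
#' @param background `"annulus"` subtracts the mean projected intensity of
#'   the annulus between 1 and 2 disc radii (local background, ImageJ
#'   style); `"none"` uses raw sums.
#' @return numeric vector of extraction percentages, one per time point.
#' @export
antigen_extraction_pct <- function(stacks, bead_cms, area_radius_um = 2.5,
                                   background = c("annulus", "none")) {
  background <- match.arg(background)
  if (length(stacks) < 1) stop("missing t = 0 acquisition")
  if (is.numeric(bead_cms) && length(bead_cms) == 3)
    bead_cms <- rep(list(bead_cms), length(stacks))
  if (length(bead_cms) != length(stacks))
    stop("bead_cms must match the number of time points")
  I <- vapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    v <- channel_volume(st, "ova")
    proj <- apply(v, c(2, 3), sum)
    vs <- st$voxel_size
    yc <- axis_centers(dim(v)[2], vs[2]); xc <- axis_centers(dim(v)[3], vs[3])
    b <- bead_cms[[i]]
    d2 <- outer((yc - b[2])^2, (xc - b[1])^2, `+`)
    sel <- d2 <= area_radius_um^2
    tot <- sum(proj[sel])
    if (background == "annulus") {
      ann <- d2 > area_radius_um^2 & d2 <= (2 * area_radius_um)^2
      if (any(ann)) tot <- tot - mean(proj[ann]) * sum(sel)
    }
    tot
  }, 0)
  if (I[1] <= 0) stop("no OVA signal at t = 0")
  pmin(pmax((1 - I / I[1]) * 100, 0), 100)
}

#' Surface mean fluorescence intensity on a sum projection
#'
#' Sum-projects the channel over z and averages it within a fixed 2D
#' region around the cell (surface BCR staining quantification).
#'
#' @param stack an `image_stack`.
#' @param role channel role (default `"bcr"`).
#' @param cell_region logical `y x x` matrix defining the fixed area.
#' @param background flat per-voxel background subtracted before
#'   projection.
#' @return mean fluorescence intensity (counts).
#' @export
surface_mfi <- function(stack, role = "bcr", cell_region, background = 0) {
  v <- channel_volume(stack, role) - background
  if (!any(cell_region)) stop("empty cell region")
  proj <- apply(v, c(2, 3), sum)
  mean(proj[cell_region])
}

#' Distance between nucleus and synapse centres in the synaptic plane
#' @param nucleus_cm,synapse_cm points `(x, y, z)` um.
#' @return Euclidean xy distance in um.
#' @export
synapse_center_distance <- function(nucleus_cm, synapse_cm) {
  sqrt(sum((nucleus_cm[1:2] - synapse_cm[1:2])^2))
}
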