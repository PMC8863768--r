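# Principal nuclear groove: detection by per-slice convex-hull deficit,
# apex localisation, depth and area.
#
# The groove of a lobed nucleus is the region inside the convex hull of a
# nuclear cross-section but outside the nucleus; slice-wise deficits are
# linked in 3D and the largest component is taken as the principal groove
# (manual delineation can override detection). Slicing runs along the
# array axis most orthogonal to the expected groove direction so the
# groove opening is visible in-plane.

# scanline fill of the 2D convex hull of a binary matrix
fill_convex_hull <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) < 3) return(m)
  hv <- chull(pts[, 1], pts[, 2])
  if (length(hv) < 3) return(m)
  pa <- pts[hv, 1]; pb <- pts[hv, 2]
  out <- m
  n <- length(hv)
  for (a in seq(min(pa), max(pa))) {
    bs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- pa[i]; a2 <- pa[j]; b1 <- pb[i]; b2 <- pb[j]
      if (a1 == a2) {
        if (a1 == a) bs <- c(bs, b1, b2)
      } else if ((a >= min(a1, a2)) && (a <= max(a1, a2))) {
        bs <- c(bs, b1 + (a - a1) * (b2 - b1) / (a2 - a1))
      }
    }
    if (length(bs)) {
      lo <- ceiling(min(bs) - 1e-7); hi <- floor(max(bs) + 1e-7)
      if (hi >= lo) out[a, lo:hi] <- TRUE
    }
  }
  out
}

# Choose the slicing axis (1=z, 2=y, 3=x) for a groove expected to open
# along hint (x, y, z): slices must be orthogonal to the groove cylinder.
# For mostly in-plane grooves (bead conjugates) slice along z; for mostly
# axial grooves (coverslip synapses) slice along the in-plane axis most
# orthogonal to the hint.
slice_axis_for <- function(hint_xyz) {
  h <- abs(hint_xyz) / max(vnorm(hint_xyz), 1e-12)
  if (h[3] < 0.707) return(1L)
  if (h[1] <= h[2]) 3L else 2L
}

# physical (x, y, z) coordinates of permuted-frame voxel indices
perm_idx_to_phys <- function(idx_perm, perm, voxel_size) {
  orig <- matrix(0, nrow(idx_perm), 3)
  orig[, perm] <- idx_perm
  cbind(x = (orig[, 3] - 0.5) * voxel_size[3],
        y = (orig[, 2] - 0.5) * voxel_size[2],
        z = (orig[, 1] - 0.5) * voxel_size[1])
}

#' Detect the principal nuclear groove
#'
#' Per slice, the groove candidate region is the 2D convex hull of the
#' nuclear cross-section minus the nucleus; slice deficits are linked in
#' 3D (6-connectivity) and the largest component above a minimal volume is
#' the principal groove. The lobe apices are the two nucleus boundary
#' points at the ends of the groove opening on the hull; the depth point is
#' the groove point farthest from the apex baseline (evaluated in the
#' slice of maximal groove cross-section). A manual ROI mask overrides
#' detection (`source = "manual"`).
#'
#' @param nucleus_mask `mask3d` of the segmented nucleus.
#' @param hint_direction optional expected groove direction `(x, y, z)`;
#'   used only to orient the slicing axis, never to select the component.
#' @param slice_axis optional explicit slicing axis (1 = z, 2 = y, 3 = x).
#' @param manual_roi optional `mask3d` delineating the groove manually.
#' @param min_volume_um3 minimal deficit volume considered a concavity.
#' @return object of class `groove_geometry` with the groove mask, groove
#'   centre of mass, lobe apices, depth point and bookkeeping of the
#'   representative slice.
#' @export
detect_groove <- function(nucleus_mask, hint_direction = NULL,
                          slice_axis = NULL, manual_roi = NULL,
                          min_volume_um3 = 0.05) {
  stopifnot(inherits(nucleus_mask, "mask3d"))
  if (!any(nucleus_mask$voxels)) stop("empty nucleus mask")
  vs <- nucleus_mask$voxel_size
  axis <- slice_axis %||%
    (if (!is.null(hint_direction)) slice_axis_for(hint_direction) else 1L)
  perm <- c(axis, setdiff(1:3, axis))
  W <- aperm(nucleus_mask$voxels, perm)
  vs_perm <- vs[perm]
  dmp <- dim(W)

  if (!is.null(manual_roi)) {
    D <- aperm(manual_roi$voxels, perm)
    source <- "manual"
  } else {
    D <- array(FALSE, dmp)
    for (i in seq_len(dmp[1])) {
      sl <- W[i, , ]
      if (sum(sl) >= 3) D[i, , ] <- fill_convex_hull(sl) & !sl
    }
    source <- "auto"
  }
  if (!any(D)) stop("no groove found: nucleus has no concavity")
  regs <- connected_components(mask3d(D, vs_perm), connectivity = 6)
  regs$table <- regs$table[regs$table$volume_um3 >= min_volume_um3, ]
  if (nrow(regs$table) == 0)
    stop("no groove found: nucleus has no concavity above the volume cutoff")
  lab <- regs$table$label[1]
  G <- regs$labels == lab
  per_slice <- apply(G, 1, sum)

  # representative slice: the slice through the groove centre of mass,
  # where the principal groove is a clean slot (near the lobe poles the
  # hull deficit blends into neighbouring inter-lobe concavities)
  gidx0 <- which(G)
  zi0 <- (gidx0 - 1L) %% dmp[1] + 1L
  rep_i <- round(mean(zi0))
  if (per_slice[rep_i] == 0) rep_i <- which.max(per_slice)
  n2 <- W[rep_i, , ]
  d2 <- if (source == "manual") D[rep_i, , ] else
    (fill_convex_hull(n2) & !n2)

  # the slot is the in-plane (4-connected) deficit component closest to
  # the groove centre of mass; lateral inter-lobe deficits are separate
  # components in the central slice
  cm2 <- c(mean(((gidx0 - 1L) %/% dmp[1]) %% dmp[2] + 1),
           mean((gidx0 - 1L) %/% (dmp[1] * dmp[2]) + 1))
  slot <- d2
  if (any(d2)) {
    lb <- EBImage::bwlabel(matrix(as.numeric(d2), nrow(d2)))
    cand <- sort(unique(lb[lb > 0]))
    dmin <- vapply(cand, function(l) {
      p <- which(lb == l, arr.ind = TRUE)
      min((p[, 1] - cm2[1])^2 + (p[, 2] - cm2[2])^2)
    }, 0)
    slot <- lb == cand[which.min(dmin)]
  }
  if (!any(slot)) slot <- G[rep_i, , ]

  # mouth: slot pixels bordering the hull exterior in the rep slice
  filled <- fill_convex_hull(n2 | d2)
  outside <- !filled
  pad <- function(m) {
    mm <- matrix(TRUE, nrow(m) + 2, ncol(m) + 2)
    mm[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    mm
  }
  po <- pad(outside)
  near_out <- matrix(FALSE, nrow(outside), ncol(outside))
  for (dy in -1:1) for (dx in -1:1)
    near_out <- near_out | po[(2 + dy):(nrow(outside) + 1 + dy),
                              (2 + dx):(ncol(outside) + 1 + dx)]
  mouth <- which(slot & near_out, arr.ind = TRUE)
  if (nrow(mouth) == 0) mouth <- which(slot, arr.ind = TRUE)
  sc <- c(vs_perm[2], vs_perm[3])
  spx_um <- sweep(which(slot, arr.ind = TRUE), 2, sc, `*`)
  npx <- which(n2, arr.ind = TRUE)
  npx_um <- sweep(npx, 2, sc, `*`)

  # apices = the two points where the nucleus touches the mouth chord.
  # The chord is the hull edge with the most slot pixels alongside it;
  # each apex is the centroid of the nucleus pixels hugging the chord on
  # its side of the mouth (robust against hull-vertex discretisation).
  apices_px <- NULL
  hv <- if (nrow(npx) >= 3) chull(npx_um[, 1], npx_um[, 2]) else integer(0)
  if (length(hv) >= 3) {
    score <- -1; chord <- NULL
    for (i in seq_along(hv)) {
      j <- if (i == length(hv)) 1L else i + 1L
      p1 <- npx_um[hv[i], ]; p2 <- npx_um[hv[j], ]
      d <- p2 - p1; L2 <- sum(d^2)
      if (L2 < 1e-9) next
      tt <- pmin(pmax(((spx_um[, 1] - p1[1]) * d[1] +
                         (spx_um[, 2] - p1[2]) * d[2]) / L2, 0), 1)
      dist2 <- (spx_um[, 1] - p1[1] - tt * d[1])^2 +
        (spx_um[, 2] - p1[2] - tt * d[2])^2
      sc_i <- sum(dist2 <= (2 * max(sc))^2)
      if (sc_i > score) { score <- sc_i; chord <- list(p1 = p1, d = d, L2 = L2) }
    }
    if (score > 0) {
      dl <- abs((npx_um[, 1] - chord$p1[1]) * chord$d[2] -
                  (npx_um[, 2] - chord$p1[2]) * chord$d[1]) / sqrt(chord$L2)
      near <- dl <= 1.5 * max(sc)
      if (sum(near) >= 2) {
        tpar <- ((npx_um[near, 1] - chord$p1[1]) * chord$d[1] +
                   (npx_um[near, 2] - chord$p1[2]) * chord$d[2]) / chord$L2
        lo <- tpar <= (min(tpar) + max(tpar)) / 2
        if (any(lo) && any(!lo)) {
          nn <- npx_um[near, , drop = FALSE]
          apices_px <- rbind(colMeans(nn[lo, , drop = FALSE]),
                             colMeans(nn[!lo, , drop = FALSE]))
        }
      }
    }
  }
  if (is.null(apices_px)) {
    # fallback: farthest-apart mouth pixels, mapped to the nucleus
    mp <- sweep(mouth, 2, sc, `*`)
    dd <- as.matrix(dist(mp))
    ij <- arrayInd(which.max(dd), dim(dd))
    ends <- mouth[as.vector(ij), , drop = FALSE]
    apex_idx <- apply(ends, 1, function(e) {
      eu <- e * sc
      which.min((npx_um[, 1] - eu[1])^2 + (npx_um[, 2] - eu[2])^2)
    })
    apices_px <- npx_um[apex_idx, , drop = FALSE]
  }
  # physical coordinates: in-plane um positions in the rep slice
  apices_idx <- cbind(rep_i, apices_px[, 1] / sc[1] + 0.5,
                      apices_px[, 2] / sc[2] + 0.5)
  apices_phys <- perm_idx_to_phys(apices_idx, perm, vs)
  apices <- list(apices_phys[1, ], apices_phys[2, ])

  gip <- cbind(zi0, ((gidx0 - 1L) %/% dmp[1]) %% dmp[2] + 1L,
               (gidx0 - 1L) %/% (dmp[1] * dmp[2]) + 1L)
  gphys <- perm_idx_to_phys(gip, perm, vs)
  groove_cm <- unname(colMeans(gphys))

  # depth point: slot pixel of the rep slice farthest from the baseline
  sidx <- which(slot, arr.ind = TRUE)
  gslice <- perm_idx_to_phys(cbind(rep_i, sidx), perm, vs)
  a1 <- apices[[1]]; a2 <- apices[[2]]
  dvec <- a2 - a1
  dn <- vnorm(dvec)
  if (dn < 1e-9) stop("degenerate groove: coincident apices")
  rel <- sweep(gslice, 2, a1)
  crossn <- sqrt(pmax(0,
    (rel[, 2] * dvec[3] - rel[, 3] * dvec[2])^2 +
    (rel[, 3] * dvec[1] - rel[, 1] * dvec[3])^2 +
    (rel[, 1] * dvec[2] - rel[, 2] * dvec[1])^2))
  depth_point <- gslice[which.max(crossn / dn), ]

  Ginv <- aperm(G, order(perm))
  structure(list(
    groove_mask = mask3d(Ginv, vs),
    groove_cm = c(x = groove_cm[1], y = groove_cm[2], z = groove_cm[3]),
    lobe_apices = apices,
    baseline = list(a1, a2),
    depth_point = depth_point,
    rep_slice = list(axis = axis, index = rep_i),
    central_area_um2 = unname(sum(slot) * vs_perm[2] * vs_perm[3]),
    per_slice_area_um2 = unname(per_slice * vs_perm[2] * vs_perm[3]),
    source = source
  ), class = "groove_geometry")
}

#' Normalised nuclear groove depth
#'
#' Depth h is the distance from the groove point farthest from the line
#' traced between the two lobe apices to that line, normalised by the cell
#' diameter (maximum Feret diameter of the cell mask in the groove's
#' representative slice).
#'
#' @param groove a `groove_geometry` from [detect_groove()].
#' @param cell_mask `mask3d` of the whole cell.
#' @return dimensionless depth `h / cell_diameter`.
#' @export
groove_depth <- function(groove, cell_mask) {
  stopifnot(inherits(groove, "groove_geometry"), inherits(cell_mask, "mask3d"))
  if (!any(cell_mask$voxels)) stop("empty cell mask")
  h <- point_line_distance(groove$depth_point, groove$baseline[[1]],
                           groove$baseline[[2]])
  axis <- groove$rep_slice$axis
  perm <- c(axis, setdiff(1:3, axis))
  W <- aperm(cell_mask$voxels, perm)
  sl <- W[groove$rep_slice$index, , ]
  pts <- which(sl, arr.ind = TRUE)
  if (nrow(pts) < 2) stop("cell mask empty in the groove slice")
  vsp <- cell_mask$voxel_size[perm]
  pum <- sweep(pts, 2, c(vsp[2], vsp[3]), `*`)
  hv <- chull(pum[, 1], pum[, 2])
  diam <- max(dist(pum[hv, , drop = FALSE]))
  h / diam
}

#' Principal groove cross-section area
#'
#' Area of the principal groove delineated in its representative
#' (central) slice, emulating manual delineation of the groove at its
#' maximum clean cross-section. Near the lobe poles the hull deficit
#' blends into neighbouring inter-lobe spaces, so the central slice - not
#' the largest raw deficit slice - is the stable analyst-like choice.
#'
#' @param nucleus_mask `mask3d` of the nucleus.
#' @param groove optional precomputed `groove_geometry`.
#' @param ... passed to [detect_groove()].
#' @return area in um^2, or `NA` with a warning when no groove exists.
#' @export
groove_area <- function(nucleus_mask, groove = NULL, ...) {
  if (is.null(groove)) {
    groove <- tryCatch(detect_groove(nucleus_mask, ...), error = function(e) {
      warning(conditionMessage(e))
      NULL
    })
    if (is.null(groove)) return(NA_real_)
  }
  groove$central_area_um2
}
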