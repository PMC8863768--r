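# Binary / labelled 3D regions: thresholding, connected components,
# slice-wise morphology, centres of mass, voxel volumes and tolerant mask
# intersections. Morphological operators work in 2D per z-slice (matching
# slice-wise confocal processing) with an optional 3D mode; pixel radii are
# interpreted on the xy pixel grid.

#' Binary 3D mask
#' @param voxels logical `z x y x x` array.
#' @param voxel_size `c(z=,y=,x=)` um.
#' @export
mask3d <- function(voxels, voxel_size) {
  stopifnot(length(dim(voxels)) == 3)
  if (!is.logical(voxels)) voxels <- array(as.logical(voxels), dim(voxels))
  structure(list(voxels = voxels,
                 voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x"))),
            class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("mask3d: %s voxels, %d foreground (%.3g um^3)\n",
              paste(dim(x$voxels), collapse = " x "), sum(x$voxels),
              mask_volume(x)))
  invisible(x)
}

# global Otsu threshold on the full-volume histogram (256 levels)
otsu_threshold <- function(v) {
  mx <- max(v)
  if (mx <= 0) return(Inf)
  m <- matrix(v / mx, ncol = 1L)
  EBImage::otsu(m, range = c(0, 1), levels = 256L) * mx
}

#' Segment one channel into a binary mask
#'
#' `method = "otsu"` thresholds at the global Otsu level of the channel
#' histogram; `"fixed"` includes voxels with intensity strictly above
#' `params$threshold`; `"percentile"` above the `params$p` quantile. A
#' function can be supplied as a pluggable pixel classifier: it receives
#' the `(z, y, x)` intensity volume and `params` and must return a logical
#' array of the same shape.
#'
#' @param stack an `image_stack`.
#' @param role channel role to segment.
#' @param method `"otsu"`, `"fixed"`, `"percentile"`, or a classifier
#'   function.
#' @param params method parameters.
#' @return a `mask3d` (empty masks produce a warning, not an error).
#' @export
segment_channel <- function(stack, role, method = "otsu", params = list()) {
  v <- channel_volume(stack, role)
  m <- if (is.function(method)) {
    res <- method(v, params)
    stopifnot(identical(dim(res), dim(v)))
    res
  } else {
    thr <- switch(method,
      otsu = otsu_threshold(v),
      fixed = params$threshold %||% stop("method 'fixed' needs params$threshold"),
      percentile = quantile(v, params$p %||% 0.99, names = FALSE),
      stop("unknown segmentation method: ", method))
    v > thr
  }
  if (!any(m)) warning(sprintf("segmentation of '%s' produced an empty mask", role))
  mask3d(m, stack$voxel_size)
}

#' Label connected 3D components
#'
#' Slices are labelled in 2D and linked across z: 6-connectivity links
#' face neighbours, 26-connectivity also edge/corner neighbours. Labels
#' are ordered by decreasing voxel count; ties are broken by lexicographic
#' (z, y, x) order of the centroid, so label 1 is always the largest
#' component.
#'
#' @param mask a `mask3d`.
#' @param connectivity 6 or 26.
#' @return object of class `labeled_regions` with fields `labels` (integer
#'   array, 0 = background) and `table` (per-label voxel count, volume in
#'   um^3, centroid in um).
#' @export
connected_components <- function(mask, connectivity = 6) {
  stopifnot(inherits(mask, "mask3d"), connectivity %in% c(6, 26))
  vox <- mask$voxels
  dm <- dim(vox)
  nz <- dm[1]
  empty_tab <- data.frame(label = integer(0), voxel_count = integer(0),
                          volume_um3 = numeric(0), centroid_x_um = numeric(0),
                          centroid_y_um = numeric(0), centroid_z_um = numeric(0))
  if (!any(vox))
    return(structure(list(labels = array(0L, dm), table = empty_tab,
                          voxel_size = mask$voxel_size),
                     class = "labeled_regions"))

  # per-slice 4-connected 2D labels (EBImage labels each frame
  # independently from 1), then offset slices to global ids
  Lf <- EBImage::bwlabel(aperm(array(as.numeric(vox), dm), c(2, 3, 1)))
  slice_max <- apply(Lf, 3, max)
  offs <- c(0, cumsum(slice_max))[seq_len(nz)]
  Lf <- Lf + rep(offs, each = dm[2] * dm[3]) * (Lf > 0)
  L <- aperm(Lf, c(3, 1, 2))
  storage.mode(L) <- "integer"
  nlab <- as.integer(sum(slice_max))

  edges <- list()
  K <- nlab + 1
  add_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel))   # encode label pairs as scalars for a fast unique()
      edges[[length(edges) + 1L]] <<- unique(a[sel] * K + b[sel])
  }
  if (connectivity == 26 && nz >= 1) {
    # in-plane diagonal links (upgrade per-slice 4- to 8-connectivity)
    add_pairs(L[, -dm[2], -dm[3], drop = FALSE], L[, -1, -1, drop = FALSE])
    add_pairs(L[, -dm[2], -1, drop = FALSE], L[, -1, -dm[3], drop = FALSE])
  }
  if (nz > 1) {
    shifts <- if (connectivity == 6) list(c(0L, 0L)) else
      asplit(as.matrix(expand.grid(dy = -1:1, dx = -1:1)), 1)
    for (s in shifts) {
      dy <- s[[1]]; dx <- s[[2]]
      ys <- seq_len(dm[2]); xs <- seq_len(dm[3])
      ya <- ys[ys + dy >= 1 & ys + dy <= dm[2]]
      xa <- xs[xs + dx >= 1 & xs + dx <= dm[3]]
      add_pairs(L[-nz, ya, xa, drop = FALSE],
                L[-1, ya + dy, xa + dx, drop = FALSE])
    }
  }
  comp <- seq_len(nlab)
  if (length(edges)) {
    code <- unique(unlist(edges))
    ed <- cbind(floor(code / K), code %% K)
    gr <- igraph::graph_from_edgelist(ed, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, nlab - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(nlab)]
  }

  idx <- which(L > 0L)
  cid <- comp[L[idx]]
  zi <- (idx - 1L) %% dm[1] + 1L
  yi <- ((idx - 1L) %/% dm[1]) %% dm[2] + 1L
  xi <- (idx - 1L) %/% (dm[1] * dm[2]) + 1L
  cnt <- tabulate(cid)
  keep <- which(cnt > 0)
  vs <- mask$voxel_size
  sums <- rowsum(cbind((zi - 0.5) * vs[1], (yi - 0.5) * vs[2],
                       (xi - 0.5) * vs[3]), cid)
  cz <- sums[, 1] / cnt[keep]; cy <- sums[, 2] / cnt[keep]
  cx <- sums[, 3] / cnt[keep]
  ord <- order(-cnt[keep], cz, cy, cx)
  relabel <- integer(max(cid))
  relabel[keep[ord]] <- seq_along(keep)

  out <- array(0L, dm)
  out[idx] <- relabel[cid]
  tab <- data.frame(label = seq_along(keep),
                    voxel_count = cnt[keep][ord],
                    volume_um3 = cnt[keep][ord] * prod(vs),
                    centroid_x_um = cx[ord], centroid_y_um = cy[ord],
                    centroid_z_um = cz[ord], row.names = NULL)
  structure(list(labels = out, table = tab, voxel_size = mask$voxel_size),
            class = "labeled_regions")
}

# mask of one labelled region
region_mask <- function(regions, label) {
  mask3d(regions$labels == label, regions$voxel_size)
}

#' Slice-wise morphological erosion / dilation
#'
#' Applies a discrete disc of the given pixel radius to every z-slice
#' (2D, matching per-slice confocal processing); `mode = "3d"` instead uses
#' an ellipsoid of the same radius in xy pixels scaled to z by the voxel
#' anisotropy. `radius_px = 0` is the identity.
#'
#' @param mask a `mask3d`.
#' @param op `"erode"` or `"dilate"`.
#' @param radius_px integer pixel radius (xy grid).
#' @param mode `"2d"` (default) or `"3d"`.
#' @export
morph_op <- function(mask, op = c("erode", "dilate"), radius_px,
                     mode = c("2d", "3d")) {
  op <- match.arg(op); mode <- match.arg(mode)
  stopifnot(inherits(mask, "mask3d"), radius_px >= 0,
            radius_px == round(radius_px))
  if (radius_px == 0) return(mask)
  vox <- mask$voxels
  if (mode == "2d") {
    brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
    fr <- aperm(array(as.numeric(vox), dim(vox)), c(2, 3, 1))
    fr <- if (op == "erode") EBImage::erode(fr, brush) else EBImage::dilate(fr, brush)
    return(mask3d(aperm(fr, c(3, 1, 2)) > 0.5, mask$voxel_size))
  }
  # 3D: shift-union (dilate) / shift-intersection (erode) over ball offsets
  vs <- mask$voxel_size
  rz <- floor(radius_px * vs[3] / vs[1])
  off <- expand.grid(dz = -rz:rz, dy = -radius_px:radius_px,
                     dx = -radius_px:radius_px)
  off <- off[(off$dz * vs[1] / vs[3])^2 + off$dy^2 + off$dx^2 <= radius_px^2, ]
  dm <- dim(vox)
  acc <- if (op == "dilate") array(FALSE, dm) else array(TRUE, dm)
  shift_arr <- function(a, dz, dy, dx, fill) {
    out <- array(fill, dim(a))
    zi <- seq_len(dm[1]); yi <- seq_len(dm[2]); xi <- seq_len(dm[3])
    zs <- zi - dz; ys <- yi - dy; xs <- xi - dx
    okz <- zs >= 1 & zs <= dm[1]; oky <- ys >= 1 & ys <= dm[2]
    okx <- xs >= 1 & xs <= dm[3]
    out[zi[okz], yi[oky], xi[okx]] <- a[zs[okz], ys[oky], xs[okx]]
    out
  }
  for (i in seq_len(nrow(off))) {
    sh <- shift_arr(vox, off$dz[i], off$dy[i], off$dx[i],
                    fill = (op == "erode"))
    acc <- if (op == "dilate") acc | sh else acc & sh
  }
  mask3d(acc, mask$voxel_size)
}

#' Centre of mass in physical coordinates
#'
#' @param x a `mask3d` (binary weighting) or an `image_stack` (intensity
#'   weighting of one channel).
#' @param role channel role when `x` is an `image_stack`.
#' @param weighting `"binary"` or `"intensity"`.
#' @param within optional `mask3d` restricting the intensity CM.
#' @param background flat background level subtracted from the intensities
#'   before weighting (not clamped, so that zero-mean noise cancels).
#' @return point `c(x, y, z)` in um.
#' @export
center_of_mass <- function(x, role = NULL,
                           weighting = c("binary", "intensity"),
                           within = NULL, background = 0) {
  weighting <- match.arg(weighting)
  if (inherits(x, "mask3d")) {
    w <- as.numeric(x$voxels)
    dm <- dim(x$voxels); vs <- x$voxel_size
  } else if (inherits(x, "image_stack")) {
    if (is.null(role)) stop("role required for an image_stack")
    v <- channel_volume(x, role)
    if (weighting == "binary") {
      w <- as.numeric(v > background)
      if (!is.null(within)) w <- w * within$voxels
    } else {
      w <- as.numeric(v - background)
      if (!is.null(within)) w <- w * within$voxels
    }
    dm <- dim(v); vs <- x$voxel_size
  } else stop("x must be a mask3d or image_stack")
  tot <- sum(w)
  if (tot <= 0) stop("empty region")
  dim(w) <- dm
  zc <- axis_centers(dm[1], vs[1]); yc <- axis_centers(dm[2], vs[2])
  xc <- axis_centers(dm[3], vs[3])
  c(x = sum(apply(w, 3, sum) * xc) / tot,
    y = sum(apply(w, 2, sum) * yc) / tot,
    z = sum(apply(w, 1, sum) * zc) / tot)
}

#' Mask volume by voxel counting
#' @param mask a `mask3d`.
#' @return volume in um^3 (`voxel_count * dz * dy * dx`).
#' @export
mask_volume <- function(mask) {
  sum(mask$voxels) * prod(mask$voxel_size)
}

#' Voxelwise intersection of two masks
#' @param a,b `mask3d` objects of identical shape.
#' @export
intersect_masks <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("mask shape mismatch: %s vs %s",
                 paste(dim(a$voxels), collapse = "x"),
                 paste(dim(b$voxels), collapse = "x")))
  mask3d(a$voxels & b$voxels, a$voxel_size)
}

#' Lamin-actin overlap fraction with pixel tolerance
#'
#' Per z-slice the lamin mask is eroded by `erosion_px` to refine
#' boundaries and the actin mask dilated by `tolerance_px` to absorb
#' diffraction-scale misregistration; the ratio of intersection to lamin
#' voxels is then pooled over slices (`pooling = "per_slice"` instead
#' averages per-slice ratios over slices with lamin signal).
#'
#' @param lamin,actin `mask3d` objects of identical shape.
#' @param erosion_px erosion radius for the lamin mask (default 1).
#' @param tolerance_px dilation radius for the actin mask (default 2); the
#'   micrometre equivalent is `tolerance_px * voxel_size["x"]`.
#' @param pooling `"pooled"` or `"per_slice"`.
#' @return fraction in `[0, 1]`; `NA` with a warning when the lamin mask is
#'   empty after erosion.
#' @export
overlap_fraction_with_tolerance <- function(lamin, actin, erosion_px = 1,
                                            tolerance_px = 2,
                                            pooling = c("pooled", "per_slice")) {
  pooling <- match.arg(pooling)
  if (!identical(dim(lamin$voxels), dim(actin$voxels)))
    stop("mask shape mismatch")
  # morphology is local: restrict to the lamin bounding box (padded by the
  # dilation radius) without changing any voxel count
  if (any(lamin$voxels)) {
    idx <- which(lamin$voxels, arr.ind = TRUE)
    pad <- tolerance_px + 1L
    dm <- dim(lamin$voxels)
    rz <- max(1L, min(idx[, 1])):min(dm[1], max(idx[, 1]))
    ry <- max(1L, min(idx[, 2]) - pad):min(dm[2], max(idx[, 2]) + pad)
    rx <- max(1L, min(idx[, 3]) - pad):min(dm[3], max(idx[, 3]) + pad)
    lamin <- mask3d(lamin$voxels[rz, ry, rx, drop = FALSE], lamin$voxel_size)
    actin <- mask3d(actin$voxels[rz, ry, rx, drop = FALSE], actin$voxel_size)
  }
  er <- morph_op(lamin, "erode", erosion_px)
  di <- morph_op(actin, "dilate", tolerance_px)
  if (!any(er$voxels)) {
    warning("lamin mask empty after erosion; overlap fraction undefined")
    return(NA_real_)
  }
  if (pooling == "pooled") {
    sum(er$voxels & di$voxels) / sum(er$voxels)
  } else {
    num <- apply(er$voxels & di$voxels, 1, sum)
    den <- apply(er$voxels, 1, sum)
    mean((num / den)[den > 0])
  }
}
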