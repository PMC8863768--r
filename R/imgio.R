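# Stack, configuration and results I/O.
#
# Internal axis order is channels x z x y x x regardless of file layout;
# voxel indices are 1-based in code, physical coordinates are voxel-centre
# positions in micrometres, and the z = 0 face is the synaptic plane
# (coverslip) in dish assays.

#' Multi-channel 3D image stack
#'
#' @param intensities numeric array, channels x z x y x x, finite and >= 0.
#' @param voxel_size voxel pitch `c(z=, y=, x=)` in micrometres.
#' @param channel_roles character vector naming each channel's role.
#' @param metadata free-form list.
#' @export
image_stack <- function(intensities, voxel_size, channel_roles,
                        metadata = list()) {
  if (length(dim(intensities)) != 4)
    stop("intensities must be a 4D channels x z x y x x array")
  if (dim(intensities)[1] != length(channel_roles))
    stop(sprintf("channel count (%d) does not match role count (%d)",
                 dim(intensities)[1], length(channel_roles)))
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  assert_pos(voxel_size, "voxel_size")
  structure(list(intensities = intensities,
                 voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
                 channel_roles = channel_roles,
                 metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d x %d (z,y,x) voxels of %s um\n",
              d[1], paste(x$channel_roles, collapse = ", "), d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Estimate the flat background level of a channel
#'
#' Mean intensity over an xy border frame of the stack (all z), where no
#' cellular structure is expected. Subtracting this level (without
#' clamping) before integrating intensities removes the positive bias that
#' detector read noise adds to sums and centres of mass.
#'
#' @param stack an `image_stack`.
#' @param role channel role.
#' @param margin_px width of the border frame in pixels.
#' @return scalar background level (counts).
#' @export
channel_background <- function(stack, role, margin_px = 4) {
  v <- channel_volume(stack, role)
  dm <- dim(v)
  m <- min(margin_px, floor(min(dm[2], dm[3]) / 4))
  sel <- array(FALSE, dm)
  sel[, c(seq_len(m), dm[2] - seq_len(m) + 1L), ] <- TRUE
  sel[, , c(seq_len(m), dm[3] - seq_len(m) + 1L)] <- TRUE
  mean(v[sel])
}

#' Extract one channel of a stack as a (z, y, x) volume
#' @param stack an `image_stack`.
#' @param role channel role label.
#' @return numeric `z x y x x` array.
#' @export
channel_volume <- function(stack, role) {
  i <- match(role, stack$channel_roles)
  if (is.na(i)) stop(sprintf("channel role '%s' not present (have: %s)",
                             role, paste(stack$channel_roles, collapse = ", ")))
  v <- stack$intensities[i, , , , drop = TRUE]
  dim(v) <- dim(stack$intensities)[2:4]
  v
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Pages are channel-major (all z of channel 1, then channel 2, ...).
#' Because baseline TIFF carries no physical calibration, a JSON sidecar
#' `<path>.json` records voxel size, channel roles and page layout;
#' [read_stack()] uses it to restore the stack exactly.
#'
#' @param stack an `image_stack`. Intensities are rounded to integers and
#'   clipped to the 16-bit range on write.
#' @param path output file (.tif).
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$intensities)
  pages <- vector("list", d[1] * d[2])
  n <- 0L
  for (ci in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      n <- n + 1L
      m <- stack$intensities[ci, zi, , ]
      dim(m) <- d[3:4]
      pages[[n]] <- pmin(pmax(round(m), 0), 65535) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  meta <- list(axes = "CZYX", size_c = d[1], size_z = d[2],
               size_y = d[3], size_x = d[4],
               voxel_size_um = as.list(stack$voxel_size),
               channel_roles = stack$channel_roles,
               metadata = stack$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Extract voxel size / dimensions from an OME-XML ImageDescription.
parse_ome_metadata <- function(desc) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  list(size_c = at("SizeC"), size_z = at("SizeZ"),
       voxel_size_um = c(z = at("PhysicalSizeZ"),
                         y = at("PhysicalSizeY"),
                         x = at("PhysicalSizeX")),
       dimension_order = xml2::xml_attr(px, "DimensionOrder"))
}

#' Read a TIFF / OME-TIFF z-stack
#'
#' Axes are normalised to channels x z x y x x. Calibration is taken from
#' the JSON sidecar written by [write_stack()] when present, otherwise from
#' OME-XML in the ImageDescription tag, otherwise from the `voxel_size` /
#' `channel_roles` arguments. 16-bit integer intensities are restored
#' exactly.
#'
#' @param path TIFF file.
#' @param voxel_size optional `c(z=,y=,x=)` um override.
#' @param channel_roles optional channel role labels.
#' @param n_channels number of channels when no metadata states it.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, voxel_size = NULL, channel_roles = NULL,
                       n_channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  if (npages == 1L && is.null(n_channels))
    warning("2D-only file: reading as a single-slice stack")

  side <- paste0(path, ".json")
  size_c <- NULL; size_z <- NULL; vz <- NULL; roles <- NULL
  meta <- list()
  channel_major <- TRUE
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    size_c <- sc$size_c; size_z <- sc$size_z
    vz <- unlist(sc$voxel_size_um)[c("z", "y", "x")]
    roles <- sc$channel_roles
    meta <- sc$metadata %||% list()
  } else {
    desc <- attr(pages[[1]], "description")
    ome <- if (!is.null(desc)) parse_ome_metadata(desc) else NULL
    if (!is.null(ome)) {
      size_c <- ome$size_c; size_z <- ome$size_z
      if (all(is.finite(ome$voxel_size_um))) vz <- ome$voxel_size_um
      # OME DimensionOrder lists the fastest-varying axis first; page order
      # across the file is the order of the slower axes after XY.
      if (!is.null(ome$dimension_order) && !is.na(ome$dimension_order))
        channel_major <- regexpr("C", ome$dimension_order) >
          regexpr("Z", ome$dimension_order)
    }
  }
  if (is.null(size_c) || !is.finite(size_c)) {
    size_c <- n_channels %||%
      (if (!is.null(channel_roles)) length(channel_roles) else 1L)
  }
  size_c <- as.integer(size_c)
  if (npages %% size_c != 0)
    stop(sprintf("page count %d is not a multiple of channel count %d",
                 npages, size_c))
  size_z <- as.integer(size_z %||% (npages / size_c))
  if (size_c * size_z != npages)
    stop("metadata SizeC * SizeZ does not match the page count")
  if (!is.null(voxel_size)) vz <- setNames(as.numeric(voxel_size), c("z", "y", "x"))
  if (is.null(vz))
    stop("missing voxel size: not in file metadata and no voxel_size override given")
  roles <- channel_roles %||% roles %||% paste0("ch", seq_len(size_c))
  if (length(roles) != size_c)
    stop(sprintf("file has %d channels but %d roles configured",
                 size_c, length(roles)))

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(size_c, size_z, ny, nx))
  bits16 <- attr(pages[[1]], "bits.per.sample") %||% 16L
  for (p in seq_len(npages)) {
    if (channel_major) {
      ci <- (p - 1L) %/% size_z + 1L
      zi <- (p - 1L) %% size_z + 1L
    } else {
      zi <- (p - 1L) %/% size_c + 1L
      ci <- (p - 1L) %% size_c + 1L
    }
    m <- pages[[p]]
    if (max(m) <= 1 && !is.integer(m)) m <- round(m * 65535)
    arr[ci, zi, , ] <- m
  }
  image_stack(arr, voxel_size = vz, channel_roles = roles, metadata = meta)
}

#' Write a scene ground-truth sidecar
#'
#' Serialises every ground-truth field of a `cell_scene` (micrometre
#' coordinates) to JSON, next to the rendered stack.
#' @param scene a `cell_scene`.
#' @param path output JSON path.
#' @export
write_scene <- function(scene, path) {
  keep <- c("cell_cm", "bead_cm", "groove_cm", "lobe_apices", "depth_point",
            "mtoc", "lysosome_centers", "nucleus_volume_true",
            "groove_depth_true", "groove_area_true", "bead_signal_per_time",
            "synapse_z", "groove_axis", "mode")
  out <- scene[keep]
  out$lysosome_centers <- unname(split(scene$lysosome_centers,
                                       row(scene$lysosome_centers)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# ---- measurement records ----------------------------------------------

RECORD_UNITS <- c(
  cell_id = "", condition = "", groove_angle_deg = "deg",
  orientation_category = "", dish_groove_angle_deg = "deg",
  lobe_rotation_deg = "deg", lobe_rotation_raw_deg = "deg",
  groove_depth_norm = "h/diameter", groove_area_um2 = "um^2",
  nucleus_volume_um3 = "um^3", actin_volume_um3 = "um^3",
  perinuclear_actin_volume_um3 = "um^3", lamin_actin_overlap_frac = "frac",
  mtoc_polarity_index = "", lamp_polarity_index = "",
  lamp_ring_frac = "frac", cluster_position = "inside/outside",
  ova_remaining_pct = "%", bcr_surface_mfi = "counts",
  nucleus_to_synapse_cm_dist_um = "um")

PROFILE_FIELDS <- c("z_profile_lamp", "z_profile_bcr", "exo70_profile")

#' Write per-cell morphometry records
#'
#' One CSV row per cell with stable column order and units recorded in
#' `#`-prefixed header comments; vector-valued profiles (z distributions,
#' radial profiles) go to a JSON sidecar `<path>.profiles.json` keyed by
#' `cell_id`.
#'
#' @param records a list of morphometry records (as returned by
#'   [analyze_cell()]), all sharing the same fields.
#' @param path output CSV path.
#' @export
write_measurements <- function(records, path) {
  if (inherits(records, "morphometry_record")) records <- list(records)
  scalar_names <- names(RECORD_UNITS)
  if (length(records) > 0) {
    keysets <- lapply(records, function(r) sort(names(r)))
    if (length(unique(vapply(keysets, paste, "", collapse = "|"))) > 1) {
      all_keys <- Reduce(union, keysets)
      common <- Reduce(intersect, keysets)
      stop("records have differing fields: ",
           paste(setdiff(all_keys, common), collapse = ", "))
    }
    scalar_names <- intersect(names(RECORD_UNITS), names(records[[1]]))
  }
  hdr <- sprintf("# %s [%s]", scalar_names, RECORD_UNITS[scalar_names])
  rows <- lapply(records, function(r) {
    vals <- lapply(scalar_names, function(k) {
      v <- r[[k]]
      if (is.null(v) || length(v) == 0) NA else v
    })
    names(vals) <- scalar_names
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(numeric(0)), length(scalar_names)),
                           scalar_names))
  con <- file(path, "w")
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  profs <- lapply(records, function(r) r[intersect(PROFILE_FIELDS, names(r))])
  names(profs) <- vapply(records, function(r) as.character(r$cell_id %||% ""), "")
  jsonlite::write_json(profs, paste0(path, ".profiles.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame of scalar measures (profiles stay in the sidecar).
#' @export
read_measurements <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- analysis configuration -------------------------------------------

ANALYSIS_DEFAULTS <- list(
  channel_role_map = NULL,
  segmentation = list(method = "otsu", thresholds = NULL),
  ring_radius_um = 3.5,
  z_slice_count = 10L,
  z_slice_step_um = 0.2,
  exo70_profile_rmax_um = 2.0,
  perinuclear_margin_um = 1.0,
  ova_area_radius_um = 2.5,
  angle_bin_edges_deg = c(0, 45, 135, 180),
  erosion_px = 1L,
  tolerance_px = 2L,
  overlap_pooling = "pooled",
  rng_seed = 1L
)

#' Analysis configuration
#'
#' Holds the fixed constants of the measurement suite: the 3.5-um lysosome
#' ring radius, the 10 x 0.2 um synaptic z-slices, the 0-2 um radial
#' profile range, the polarized / central / antipolarized angle bins, and
#' the 1-px erosion / 2-px dilation tolerance of the lamin-actin overlap.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  ov <- list(...)
  unknown <- setdiff(names(ov), names(ANALYSIS_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(ANALYSIS_DEFAULTS, ov, keep.null = TRUE)
  for (f in c("ring_radius_um", "z_slice_step_um", "exo70_profile_rmax_um",
              "perinuclear_margin_um", "ova_area_radius_um"))
    assert_pos(cfg[[f]], f)
  assert_pos(cfg$z_slice_count, "z_slice_count")
  assert_nonneg(cfg$erosion_px, "erosion_px")
  assert_nonneg(cfg$tolerance_px, "tolerance_px")
  e <- cfg$angle_bin_edges_deg
  if (length(e) < 2 || any(diff(e) <= 0) || e[1] != 0 || e[length(e)] != 180)
    stop("angle_bin_edges_deg must be strictly increasing and span [0, 180]")
  if (!cfg$overlap_pooling %in% c("pooled", "per_slice"))
    stop("overlap_pooling must be 'pooled' or 'per_slice'")
  cfg$z_slice_count <- as.integer(cfg$z_slice_count)
  cfg$erosion_px <- as.integer(cfg$erosion_px)
  cfg$tolerance_px <- as.integer(cfg$tolerance_px)
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML or JSON
#'
#' Missing keys take the built-in defaults; unknown keys are an error
#' rather than being silently ignored.
#' @param path YAML/JSON file; an empty file yields all defaults.
#' @export
load_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(analysis_config, vals)
}

#' Save an analysis configuration to YAML
#' @param config an `analysis_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
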