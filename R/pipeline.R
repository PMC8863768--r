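# Per-cell orchestration of all measures, experiment-level aggregation and
# the simulate -> analyze -> recover self-validation loop.

fill_holes_slices <- function(mask) {
  fr <- aperm(array(as.numeric(mask$voxels), dim(mask$voxels)), c(2, 3, 1))
  fr <- EBImage::fillHull(fr)
  mask3d(aperm(fr, c(3, 1, 2)) > 0.5, mask$voxel_size)
}

largest_component <- function(mask, connectivity = 6) {
  regs <- connected_components(mask, connectivity)
  if (nrow(regs$table) == 0) return(mask)
  region_mask(regs, regs$table$label[1])
}

apply_role_map <- function(stack, map) {
  if (is.null(map)) return(stack)
  m <- unlist(map)
  hit <- stack$channel_roles %in% names(m)
  stack$channel_roles[hit] <- unname(m[stack$channel_roles[hit]])
  stack
}

#' Analyze one cell: every computable measure
#'
#' Runs segmentation and the full measurement suite on a single stack.
#' Measures whose inputs are unavailable (channel absent or empty, no bead,
#' wrong mode) are set to `NA` with the reason recorded in the `"log"`
#' attribute; an absent nucleus channel is an error since most measures
#' depend on it. Deterministic for fixed inputs.
#'
#' @param stack an `image_stack`.
#' @param config an [analysis_config()].
#' @param mode `"bead"` (bead conjugate) or `"dish"` (coverslip synapse).
#' @param bead_cm optional bead centre `(x, y, z)` um; defaults to the
#'   intensity centre of mass of the `bead` channel when present.
#' @param groove_roi optional manual groove `mask3d` overriding detection.
#' @param synapse_z optional synaptic plane z (dish mode); defaults to the
#'   bottom of the cell mask.
#' @param cell_id identifier copied into the record.
#' @return a `morphometry_record` (named list; vector-valued profiles under
#'   `z_profile_lamp`, `z_profile_bcr`, `exo70_profile`).
#' @export
analyze_cell <- function(stack, config = analysis_config(),
                         mode = c("bead", "dish"), bead_cm = NULL,
                         groove_roi = NULL, synapse_z = NULL,
                         cell_id = "cell1") {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  stack <- apply_role_map(stack, config$channel_role_map)
  roles <- stack$channel_roles
  vol_cache <- new.env(parent = emptyenv())
  chan <- function(role) {
    if (is.null(vol_cache[[role]]))
      vol_cache[[role]] <- channel_volume(stack, role)
    vol_cache[[role]]
  }
  nonzero <- function(role) role %in% roles && sum(chan(role)) > 0
  if (!nonzero("nucleus"))
    stop("no nucleus channel: the nucleus is required by most measures")

  log <- character(0)
  note <- function(field, why) log <<- c(log, sprintf("%s: %s", field, why))
  try_na <- function(field, expr, na = NA_real_) {
    tryCatch(withCallingHandlers(expr,
               warning = function(w) {
                 note(field, conditionMessage(w))
                 invokeRestart("muffleWarning")
               }),
             error = function(e) { note(field, conditionMessage(e)); na })
  }

  seg <- function(role) {
    thr <- config$segmentation$thresholds[[role]]
    if (!is.null(thr))
      segment_channel(stack, role, "fixed", list(threshold = thr))
    else segment_channel(stack, role, config$segmentation$method)
  }

  border_bg <- function(v, margin_px = 4) {
    dm <- dim(v)
    m <- min(margin_px, floor(min(dm[2], dm[3]) / 4))
    mean(c(v[, c(seq_len(m), dm[2] - seq_len(m) + 1L), ],
           v[, , c(seq_len(m), dm[3] - seq_len(m) + 1L)]))
  }
  bg <- vapply(setNames(roles, roles), function(r)
    if (nonzero(r)) border_bg(chan(r)) else 0, 0)

  nucleus_mask <- fill_holes_slices(largest_component(seg("nucleus")))
  actin_raw <- if (nonzero("actin")) seg("actin") else NULL
  cell_mask <- if (!is.null(actin_raw))
    largest_component(fill_holes_slices(actin_raw)) else NULL
  cell_cm <- if (!is.null(cell_mask)) center_of_mass(cell_mask) else
    center_of_mass(nucleus_mask)
  nucleus_cm <- center_of_mass(nucleus_mask)

  if (is.null(bead_cm) && nonzero("bead"))
    bead_cm <- center_of_mass(stack, "bead", "intensity", background = bg[["bead"]])
  if (is.null(bead_cm)) note("bead_cm", "no bead channel or coordinates")

  mtoc <- NULL
  if (nonzero("tubulin")) {
    v <- chan("tubulin")
    spot <- mask3d(v >= 0.5 * max(v), stack$voxel_size)
    mtoc <- try_na("mtoc", center_of_mass(stack, "tubulin", "intensity",
                                          within = spot,
                                          background = bg[["tubulin"]]), na = NULL)
  } else note("mtoc", "no tubulin channel")

  if (mode == "dish" && is.null(synapse_z)) {
    base <- if (!is.null(cell_mask)) cell_mask else nucleus_mask
    zmin <- which(apply(base$voxels, 1, any))[1]
    synapse_z <- (zmin - 1) * stack$voxel_size[1]
  }

  hint <- if (mode == "bead" && !is.null(bead_cm)) bead_cm - cell_cm else
    c(0, 0, -1)
  groove <- try_na("groove",
                   detect_groove(nucleus_mask, hint_direction = hint,
                                 manual_roi = groove_roi), na = NULL)

  rec <- list(cell_id = cell_id)
  rec$groove_angle_deg <- if (mode == "bead" && !is.null(bead_cm) &&
                              !is.null(groove))
    try_na("groove_angle_deg",
           groove_orientation_bead(bead_cm, cell_cm, groove$groove_cm))
  else NA_real_
  rec$orientation_category <- if (is.finite(rec$groove_angle_deg))
    classify_orientation(rec$groove_angle_deg, config$angle_bin_edges_deg)
  else NA_character_
  rec$dish_groove_angle_deg <- if (mode == "dish" && !is.null(groove))
    try_na("dish_groove_angle_deg",
           groove_orientation_dish(cell_cm, groove$groove_cm, synapse_z))
  else NA_real_
  if (mode == "dish" && !is.null(groove)) {
    lr <- try_na("lobe_rotation",
                 lobe_rotation(groove$lobe_apices, synapse_z), na = NULL)
    rec$lobe_rotation_deg <- if (!is.null(lr)) lr$angle_deg else NA_real_
    rec$lobe_rotation_raw_deg <- if (!is.null(lr)) lr$raw_deg else NA_real_
  } else {
    rec$lobe_rotation_deg <- NA_real_
    rec$lobe_rotation_raw_deg <- NA_real_
  }
  rec$groove_depth_norm <- if (!is.null(groove) && !is.null(cell_mask))
    try_na("groove_depth_norm", groove_depth(groove, cell_mask))
  else NA_real_
  rec$groove_area_um2 <- if (!is.null(groove))
    try_na("groove_area_um2", groove_area(nucleus_mask, groove = groove))
  else NA_real_

  rec$nucleus_volume_um3 <- mask_volume(nucleus_mask)
  rec$actin_volume_um3 <- if (!is.null(actin_raw)) mask_volume(actin_raw)
    else NA_real_
  rec$perinuclear_actin_volume_um3 <- if (!is.null(actin_raw))
    try_na("perinuclear_actin_volume_um3",
           mask_volume(intersect_masks(actin_raw, nucleus_mask)))
  else NA_real_
  rec$lamin_actin_overlap_frac <- if (!is.null(actin_raw))
    try_na("lamin_actin_overlap_frac",
           overlap_fraction_with_tolerance(nucleus_mask, actin_raw,
                                           config$erosion_px,
                                           config$tolerance_px,
                                           config$overlap_pooling))
  else NA_real_

  rec$mtoc_polarity_index <- if (!is.null(mtoc) && !is.null(bead_cm))
    try_na("mtoc_polarity_index",
           polarity_index(mtoc, cell_cm, bead_cm)$index)
  else NA_real_
  lamp_on <- nonzero("lamp1")
  rec$lamp_polarity_index <- if (lamp_on && !is.null(bead_cm))
    try_na("lamp_polarity_index",
           polarity_index(center_of_mass(stack, "lamp1", "intensity",
                                         within = cell_mask,
                                         background = bg[["lamp1"]]),
                          cell_cm, bead_cm)$index)
  else NA_real_
  rec$lamp_ring_frac <- if (lamp_on && !is.null(bead_cm))
    try_na("lamp_ring_frac",
           lamp_ring_fraction(stack, bead_cm, config$ring_radius_um,
                              cell_mask = cell_mask,
                              background = bg[["lamp1"]]))
  else NA_real_

  zready <- mode == "dish" && !is.null(synapse_z)
  rec$z_profile_lamp <- if (lamp_on && zready)
    try_na("z_profile_lamp",
           z_distribution(stack, "lamp1", synapse_z, config$z_slice_count,
                          config$z_slice_step_um, cell_mask,
                          background = bg[["lamp1"]]),
           na = rep(NA_real_, config$z_slice_count))
  else rep(NA_real_, config$z_slice_count)
  rec$z_profile_bcr <- if (nonzero("bcr") && zready)
    try_na("z_profile_bcr",
           z_distribution(stack, "bcr", synapse_z, config$z_slice_count,
                          config$z_slice_step_um, cell_mask,
                          background = bg[["bcr"]]),
           na = rep(NA_real_, config$z_slice_count))
  else rep(NA_real_, config$z_slice_count)

  rec$cluster_position <- if (lamp_on)
    try_na("cluster_position",
           cluster_position(seg("lamp1"), nucleus_mask,
                            config$perinuclear_margin_um),
           na = NA_character_)
  else NA_character_

  rec$exo70_profile <- if (nonzero("exo70") && !is.null(mtoc))
    try_na("exo70_profile",
           radial_profile(stack, "exo70", mtoc, config$exo70_profile_rmax_um),
           na = NULL)
  else NULL

  rec$ova_remaining_pct <- NA_real_   # defined on time courses only

  rec$bcr_surface_mfi <- if (nonzero("bcr") && !is.null(cell_mask)) {
    try_na("bcr_surface_mfi", {
      foot <- apply(cell_mask$voxels, c(2, 3), any)
      grow <- ceiling(0.5 / stack$voxel_size[3])
      region <- EBImage::dilate(matrix(as.numeric(foot), nrow(foot)),
                                EBImage::makeBrush(2L * grow + 1L, "disc")) > 0.5
      surface_mfi(stack, "bcr", region, background = bg[["bcr"]])
    })
  } else NA_real_

  rec$nucleus_to_synapse_cm_dist_um <- if (zready && !is.null(actin_raw)) {
    try_na("nucleus_to_synapse_cm_dist_um", {
      dz <- stack$voxel_size[1]
      zc <- axis_centers(dim(actin_raw$voxels)[1], dz)
      slab <- mask3d(actin_raw$voxels &
                       array(zc < synapse_z + 0.6, dim(actin_raw$voxels)),
                     stack$voxel_size)
      synapse_cm <- center_of_mass(stack, "actin", "intensity", within = slab,
                                   background = bg[["actin"]])
      synapse_center_distance(nucleus_cm, synapse_cm)
    })
  } else NA_real_

  structure(rec, class = "morphometry_record", log = log)
}

#' Run the analysis over an experiment manifest
#'
#' @param manifest data.frame with columns `stack_path`, `condition`,
#'   `mode`, and optionally `bead_x`, `bead_y`, `bead_z`, `roi_path`.
#' @param config an [analysis_config()].
#' @param out_dir optional directory for the per-cell CSV and summary.
#' @return list with `cells` (per-cell data.frame), `summary`
#'   (per-condition n, means, medians and orientation-category
#'   percentages; no statistical testing) and `failures`.
#' @export
run_experiment <- function(manifest, config = analysis_config(),
                           out_dir = NULL) {
  manifest <- as.data.frame(manifest)
  if (nrow(manifest) == 0) stop("empty manifest")
  stopifnot(all(c("stack_path", "condition", "mode") %in% names(manifest)))
  if (any(!nzchar(manifest$condition))) stop("empty condition label")
  if (any(!manifest$mode %in% c("bead", "dish")))
    stop("manifest mode must be 'bead' or 'dish'")
  missing <- !file.exists(manifest$stack_path)
  if (any(missing))
    stop("missing stack file(s): ",
         paste(manifest$stack_path[missing], collapse = ", "))

  records <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- read_stack(row$stack_path)
      bead <- if (all(c("bead_x", "bead_y", "bead_z") %in% names(row)) &&
                  is.finite(row$bead_x))
        c(row$bead_x, row$bead_y, row$bead_z) else NULL
      roi <- if ("roi_path" %in% names(row) && !is.na(row$roi_path) &&
                 nzchar(row$roi_path))
        read_stack(row$roi_path) else NULL
      roi_mask <- if (!is.null(roi))
        mask3d(channel_volume(roi, roi$channel_roles[1]) > 0, roi$voxel_size)
      else NULL
      rec <- analyze_cell(stack, config, mode = row$mode, bead_cm = bead,
                          groove_roi = roi_mask,
                          cell_id = basename(row$stack_path))
      rec$condition <- row$condition
      rec
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", row$stack_path,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) records[[length(records) + 1L]] <- res
  }
  if (length(records) == 0)
    stop("all cells failed:\n", paste(failures, collapse = "\n"))

  scalar_names <- intersect(names(RECORD_UNITS), names(records[[1]]))
  cells <- do.call(rbind, lapply(records, function(r)
    as.data.frame(lapply(setNames(scalar_names, scalar_names), function(k)
      r[[k]] %||% NA), stringsAsFactors = FALSE)))

  summarize <- function(df) {
    nums <- names(df)[vapply(df, is.numeric, TRUE)]
    out <- data.frame(n = nrow(df))
    for (k in nums) {
      out[[paste0("mean_", k)]] <- mean(df[[k]], na.rm = TRUE)
      out[[paste0("median_", k)]] <- median(df[[k]], na.rm = TRUE)
    }
    cats <- df$orientation_category
    for (cat in c("Polarized", "Central", "Antipolarized"))
      out[[paste0("pct_", tolower(cat))]] <-
        100 * mean(cats == cat, na.rm = TRUE)
    out
  }
  summary <- do.call(rbind, lapply(split(cells, cells$condition), summarize))
  summary <- cbind(condition = rownames(summary), summary, row.names = NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measurements(records, file.path(out_dir, "cells.csv"))
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (length(failures))
      writeLines(failures, file.path(out_dir, "failures.log"))
  }
  list(cells = cells, summary = summary, failures = failures)
}

# scene/analysis settings used throughout validation: same physical scene
# as the defaults but sampled at 0.2 x 0.15 x 0.15 um so that a full
# recovery grid stays desk-scale (see the methods vignette).
validation_base <- function(seed, noise, ...) {
  scene_config(voxel_size = c(z = 0.2, y = 0.15, x = 0.15),
               stack_shape = c(z = 60, y = 88, x = 108),
               noise = if (noise) list(poisson_scale = 1, gaussian_sd = 5)
                       else list(poisson_scale = 0, gaussian_sd = 0),
               rng_seed = seed, ...)
}

#' Simulate -> analyze -> recover validation loop
#'
#' Simulates phantoms over a grid of ground-truth parameters (MTOC
#' polarity offsets, groove orientations, groove depths, lysosome ring
#' fractions, antigen-extraction time courses), runs the full analysis
#' pipeline on the rendered stacks and reports bias and RMSE per measure
#' against the analytic ground truth.
#'
#' @param seed integer seed; the whole report is deterministic given it.
#' @param n_per_condition phantoms per grid setting (default 20).
#' @param noise render with Poisson + Gaussian noise (default) or
#'   noise-free.
#' @return data.frame with one row per (measure, setting): truth, mean
#'   estimate, bias, RMSE, tolerance and pass flag; attribute `"pass"`
#'   summarises the whole grid.
#' @export
validate <- function(seed = 1, n_per_condition = 20, noise = TRUE) {
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (seed * 10007L + counter) %% 2147483647L
  }
  amps0 <- setNames(rep(0, 8), CHANNEL_ROLES)
  rows <- list()
  add <- function(measure, setting, truth, est, tol) {
    est <- est[is.finite(est)]
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, setting = setting, truth = truth,
      mean_est = mean(est), bias = mean(est) - truth,
      rmse = sqrt(mean((est - truth)^2)), n = length(est), tol = tol,
      pass = is.finite(mean(est)) && abs(mean(est) - truth) <= tol)
  }
  run_one <- function(cfg, mode = "bead") {
    scene <- make_scene(cfg)
    stack <- render_stack(scene, cfg)
    list(scene = scene,
         record = analyze_cell(stack, mode = mode))
  }

  for (off in c(-1, -0.5, 0, 0.5, 1)) {
    amps <- amps0; amps[c("actin", "tubulin", "bead", "nucleus")] <- 500
    est <- vapply(seq_len(n_per_condition), function(i) {
      cfg <- validation_base(next_seed(), noise, mtoc_offset = off,
                             channel_amplitudes = amps)
      run_one(cfg)$record$mtoc_polarity_index
    }, 0)
    add("mtoc_polarity_index", sprintf("offset=%+.1f", off), off, est, 0.05)
  }

  for (ang in c(0, 30, 60, 90, 135, 180)) {
    amps <- amps0; amps[c("nucleus", "actin", "bead")] <- 500
    est <- vapply(seq_len(n_per_condition), function(i) {
      cfg <- validation_base(next_seed(), noise, groove_orientation = ang,
                             channel_amplitudes = amps)
      run_one(cfg)$record$groove_angle_deg
    }, 0)
    add("groove_angle_deg", sprintf("angle=%d", ang), ang, est, 2)
  }

  for (fr in c(0.1, 0.2, 0.3)) {
    amps <- amps0; amps[c("nucleus", "actin", "bead")] <- 500
    est <- vapply(seq_len(n_per_condition), function(i) {
      cfg <- validation_base(next_seed(), noise, groove_depth_frac = fr,
                             channel_amplitudes = amps)
      run_one(cfg)$record$groove_depth_norm
    }, 0)
    add("groove_depth_norm", sprintf("frac=%.1f", fr), fr, est, 0.03)
  }

  {
    amps <- amps0; amps[c("nucleus", "actin", "lamp1", "bead")] <- 500
    err <- vapply(seq_len(n_per_condition), function(i) {
      cfg <- validation_base(next_seed(), noise,
                             lysosome_mode = "perinuclear",
                             channel_amplitudes = amps)
      res <- run_one(cfg)
      res$record$lamp_ring_frac - scene_ring_fraction(res$scene)
    }, 0)
    add("lamp_ring_frac", "perinuclear", 0, err, 0.05)
  }

  fracs <- c(0, 0.25, 0.60)
  amps <- amps0; amps[c("ova", "bead")] <- 500
  ext_est <- vapply(seq_len(n_per_condition), function(i) {
    cfg <- scene_config(voxel_size = c(z = 0.5, y = 0.2, x = 0.2),
                        stack_shape = c(z = 26, y = 66, x = 82),
                        noise = if (noise) list(poisson_scale = 1,
                                                gaussian_sd = 5)
                                else list(poisson_scale = 0, gaussian_sd = 0),
                        channel_amplitudes = amps, rng_seed = next_seed())
    tc <- make_timecourse(cfg, times = c(0, 30, 60), extraction_fracs = fracs)
    stacks <- lapply(tc, `[[`, "stack")
    bead <- center_of_mass(stacks[[1]], "bead", "intensity")
    antigen_extraction_pct(stacks, bead)
  }, numeric(3))
  for (j in seq_along(fracs))
    add("antigen_extraction_pct", sprintf("frac=%.2f", fracs[j]),
        100 * fracs[j], ext_est[j, ], 2)

  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}
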