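# Stack, measurement and configuration I/O.

test_that("stack write/read round trip preserves integer intensities", {
  arr <- array(0, c(2, 3, 8, 9))
  arr[1, , , ] <- sample(0:65535, 3 * 8 * 9, replace = TRUE)
  arr[2, , , ] <- sample(0:2000, 3 * 8 * 9, replace = TRUE)
  st <- image_stack(arr, voxel_size = c(0.2, 0.07, 0.07),
                    channel_roles = c("nucleus", "actin"))
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$intensities, st$intensities)
  expect_equal(back$voxel_size, st$voxel_size)
  expect_equal(back$channel_roles, st$channel_roles)
})

test_that("channel/role mismatch and missing voxel size are errors", {
  arr <- array(1, c(3, 2, 4, 4))
  st <- image_stack(arr, c(0.2, 0.1, 0.1), c("a", "b", "c"))
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  expect_error(read_stack(path, channel_roles = c("a", "b", "c", "d")),
               "3 channels but 4 roles")
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path, n_channels = 3), "missing voxel size")
  expect_error(image_stack(arr, c(0.2, 0.1, 0.1), c("a", "b")),
               "does not match")
})

test_that("OME-XML pixel metadata is parsed", {
  ome <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels SizeC="3" SizeZ="10" SizeX="64" SizeY="64" SizeT="1" ',
    'PhysicalSizeX="0.07" PhysicalSizeY="0.07" PhysicalSizeZ="0.2" ',
    'DimensionOrder="XYCZT"/></Image></OME>')
  meta <- synmorph:::parse_ome_metadata(ome)
  expect_equal(meta$voxel_size_um[["x"]], 0.07)
  expect_equal(meta$voxel_size_um[["y"]], 0.07)
  expect_equal(meta$voxel_size_um[["z"]], 0.2)
  expect_equal(meta$size_c, 3)
  expect_equal(meta$size_z, 10)
})

test_that("2D-only files load as single-slice stacks with a warning", {
  m <- matrix(runif(12), 3, 4)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m, path)
  expect_warning(st <- read_stack(path, voxel_size = c(0.5, 0.1, 0.1)),
                 "single-slice")
  expect_equal(dim(st$intensities), c(1L, 1L, 3L, 4L))
})

test_that("measurement tables round-trip and reject mismatched records", {
  recs <- lapply(1:3, function(i) {
    structure(list(cell_id = paste0("c", i),
                   groove_angle_deg = runif(1, 0, 180),
                   mtoc_polarity_index = runif(1, -1, 1),
                   nucleus_volume_um3 = 150 + i * exp(1),
                   z_profile_lamp = rep(10, 10)),
              class = "morphometry_record")
  })
  path <- tempfile(fileext = ".csv")
  write_measurements(recs, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$nucleus_volume_um3, vapply(recs, `[[`, 0, "nucleus_volume_um3"),
               tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".profiles.json")))

  bad <- recs
  bad[[2]]$extra_field <- 1
  expect_error(write_measurements(bad, path), "differing fields")

  # empty record list: header-only CSV, not an error
  write_measurements(list(), path)
  expect_equal(nrow(read_measurements(path)), 0)
})

test_that("analysis configuration defaults, validation and round trip", {
  cfg <- analysis_config()
  expect_equal(cfg$ring_radius_um, 3.5)
  expect_equal(cfg$z_slice_count, 10L)
  expect_equal(cfg$z_slice_step_um, 0.2)
  expect_equal(cfg$exo70_profile_rmax_um, 2.0)
  expect_equal(cfg$angle_bin_edges_deg, c(0, 45, 135, 180))
  expect_equal(cfg$erosion_px, 1L)
  expect_equal(cfg$tolerance_px, 2L)

  # empty YAML -> all defaults
  path <- tempfile(fileext = ".yaml")
  writeLines("", path)
  expect_equal(load_config(path), cfg)

  expect_error(analysis_config(ring_radius_um = -1), "ring_radius_um")
  expect_error(analysis_config(nonsense_key = 1), "unknown configuration key")
  expect_equal(analysis_config(z_slice_step_um = 0.5)$z_slice_step_um, 0.5)

  # load -> save -> load is identity
  cfg2 <- analysis_config(z_slice_step_um = 0.5, tolerance_px = 3)
  save_config(cfg2, path)
  expect_equal(load_config(path), cfg2)
})
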