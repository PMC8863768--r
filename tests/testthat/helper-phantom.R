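# Shared phantom builders for the tests: the default physical scene
# sampled at 0.2 x 0.15 x 0.15 um so unit tests stay fast. Channels not
# named in `on` are rendered empty.

test_config <- function(seed = 1, noise = FALSE,
                        on = c("nucleus", "actin", "bead"), ...) {
  amps <- setNames(rep(0, 8), c("nucleus", "actin", "tubulin", "lamp1",
                                "ova", "exo70", "bcr", "bead"))
  amps[on] <- 500
  scene_config(voxel_size = c(z = 0.2, y = 0.15, x = 0.15),
               stack_shape = c(z = 60, y = 88, x = 108),
               channel_amplitudes = amps,
               noise = if (noise) list(poisson_scale = 1, gaussian_sd = 5)
                       else list(poisson_scale = 0, gaussian_sd = 0),
               rng_seed = seed, ...)
}

# rasterize the analytic nucleus of a scene directly (no PSF, no noise),
# at the voxel grid of an arbitrary config
rasterize_nucleus <- function(scene, config = scene$config) {
  g <- synmorph:::voxel_grid(config$stack_shape, config$voxel_size)
  ctr <- scene$cell_cm
  Rt <- t(scene$rotation)
  qx <- Rt[1, 1] * (g$X - ctr[1]) + Rt[1, 2] * (g$Y - ctr[2]) + Rt[1, 3] * (g$Z - ctr[3])
  qy <- Rt[2, 1] * (g$X - ctr[1]) + Rt[2, 2] * (g$Y - ctr[2]) + Rt[2, 3] * (g$Z - ctr[3])
  qz <- Rt[3, 1] * (g$X - ctr[1]) + Rt[3, 2] * (g$Y - ctr[2]) + Rt[3, 3] * (g$Z - ctr[3])
  mask3d(synmorph:::inside_nucleus_canonical(qx, qy, qz, scene$geom),
         config$voxel_size)
}

rasterize_cell <- function(scene, config = scene$config) {
  g <- synmorph:::voxel_grid(config$stack_shape, config$voxel_size)
  ctr <- scene$cell_cm
  mask3d((g$X - ctr[1])^2 + (g$Y - ctr[2])^2 + (g$Z - ctr[3])^2 <=
           config$cell_radius^2, config$voxel_size)
}

# order-free apex comparison: smallest total matching distance
apex_error <- function(detected, truth) {
  d1 <- synmorph:::vnorm(detected[[1]] - truth[[1]]) +
    synmorph:::vnorm(detected[[2]] - truth[[2]])
  d2 <- synmorph:::vnorm(detected[[1]] - truth[[2]]) +
    synmorph:::vnorm(detected[[2]] - truth[[1]])
  min(d1, d2) / 2
}

# minimal image_stack around a raw (z, y, x) volume for one role
stack_of <- function(vol, role, voxel = c(0.2, 0.15, 0.15)) {
  arr <- array(0, c(1, dim(vol)))
  arr[1, , , ] <- vol
  image_stack(arr, voxel_size = voxel, channel_roles = role)
}
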