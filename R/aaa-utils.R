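# Shared geometry and array helpers. Physical points are length-3 numeric
# vectors in (x, y, z) order, micrometres; voxel arrays are indexed
# (z, y, x); voxel_size is named c(z=, y=, x=). The centre of voxel
# (iz, iy, ix) (1-based) sits at ((ix-0.5)*dx, (iy-0.5)*dy, (iz-0.5)*dz).

`%||%` <- function(a, b) if (is.null(a)) b else a

CHANNEL_ROLES <- c("nucleus", "actin", "tubulin", "lamp1", "ova",
                   "exo70", "bcr", "bead")

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

#' Angle between two vectors, in degrees
#'
#' @param u,v numeric length-3 vectors (any nonzero length works).
#' @return angle in `[0, 180]` degrees.
#' @export
angle_between_deg <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: zero-length vector")
  ct <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ct))) * 180 / pi
}

# Rotation about the z axis (degrees), acting on (x, y, z) column vectors.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

# Orientation for the coverslip (dish) geometry: maps the canonical groove
# axis +x to (0, sin(rho), -cos(rho)) and the apex baseline +y to
# (0, cos(rho), sin(rho)). rho = 0 means the groove faces the synaptic
# plane (fully rotated); rho = 90 means the lobes are stacked vertically.
rot_dish <- function(rho_deg) {
  r <- rho_deg * pi / 180
  cbind(c(0, sin(r), -cos(r)),
        c(0, cos(r), sin(r)),
        c(1, 0, 0))
}

axis_centers <- function(n, d) (seq_len(n) - 0.5) * d

# World-coordinate arrays for a (z, y, x) voxel grid; returns list of three
# arrays X, Y, Z each of dim (nz, ny, nx), in micrometres.
voxel_grid <- function(stack_shape, voxel_size) {
  nz <- stack_shape[[1]]; ny <- stack_shape[[2]]; nx <- stack_shape[[3]]
  zc <- axis_centers(nz, voxel_size[[1]])
  yc <- axis_centers(ny, voxel_size[[2]])
  xc <- axis_centers(nx, voxel_size[[3]])
  dm <- c(nz, ny, nx)
  list(X = array(rep(xc, each = nz * ny), dm),
       Y = array(rep(rep(yc, each = nz), times = nx), dm),
       Z = array(zc, dm))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive, got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
}

assert_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
}

# Distance from point p to the infinite line through a and b (all (x,y,z)).
point_line_distance <- function(p, a, b) {
  d <- b - a
  n <- vnorm(d)
  if (n < 1e-12) stop("degenerate geometry: coincident line points")
  vnorm(pracma_cross(p - a, d)) / n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
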