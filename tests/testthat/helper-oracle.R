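# Independent brute-force oracles over the analytic scene geometry. These
# recompute ground-truth quantities through a different route than
# make_scene (membership bisection + independent quadrature / grid
# sampling) so that stored scene values can be cross-checked.

# groove half-width at (x, z) by bisection on the nucleus membership test
oracle_groove_halfwidth <- function(x, z, geom, ymax = 6) {
  vapply(x, function(xx) {
    inside <- function(y)
      synmorph:::inside_nucleus_canonical(xx, y, z, geom)
    # first nuclear material walking up from the groove mid-plane
    ys <- seq(0, ymax, by = 0.01)
    hit <- which(inside(ys))[1]
    if (is.na(hit)) return(0)
    if (hit == 1L) return(0)
    lo <- ys[hit - 1L]; hi <- ys[hit]
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (inside(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, 0)
}

# nucleus volume by nested adaptive quadrature of the direct z-chord
# (max over lobes, wedge cut), independent of the piecewise-analytic
# segment decomposition used in make_scene. The inner integral skips the
# wedge channel (chord identically zero for |y| < t(x)) so the integrand
# is continuous on the integration range.
oracle_nucleus_volume <- function(geom) {
  xmax <- max(geom$lobe_centers[, 1] + geom$lobe_radii)
  xmin <- min(geom$lobe_centers[, 1] - geom$lobe_radii)
  ymax <- max(abs(geom$lobe_centers[, 2]) + geom$lobe_radii)
  slice <- function(x) {
    t <- if (x > geom$x_w) max(geom$w_min, (x - geom$x_w) * geom$tanb) else 0
    if (t >= ymax) return(0)
    2 * integrate(function(y) synmorph:::nucleus_z_chord(x, y, geom),
                  t, ymax, subdivisions = 400L, rel.tol = 1e-9,
                  stop.on.error = FALSE)$value
  }
  integrate(function(x) vapply(x, slice, 0), xmin, xmax,
            subdivisions = 800L, rel.tol = 1e-8,
            stop.on.error = FALSE)$value
}

# groove mid-plane section area / centroid via the bisection half-width
oracle_groove_section <- function(geom, n = 4000) {
  xs <- seq(geom$x_w + 1e-9, geom$xA - 1e-9, length.out = n)
  yup <- oracle_groove_halfwidth(xs, 0, geom)
  dx <- xs[2] - xs[1]
  area <- sum(2 * yup) * dx
  cmx <- sum(xs * 2 * yup) * dx / area
  list(area = area, cm_x = cmx)
}
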