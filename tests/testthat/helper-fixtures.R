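# Fixtures are built in code at test time; nothing is read from disk except
# the small phantom repeatability summary shipped under inst/extdata.

cube_corners <- function() {
  point_cloud(as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))))
}

random_cloud <- function(n, seed = 1, scale = 100) {
  set.seed(seed)
  point_cloud(matrix(stats::runif(3 * n, 0, scale), ncol = 3))
}

plane_cloud <- function(step = 3, extent = 90, z = 0) {
  g <- expand.grid(x = seq(0, extent, step), y = seq(0, extent, step))
  point_cloud(cbind(g$x, g$y, z))
}

# upper cap of a sphere of given radius centred on the z axis, seen from the
# sensor (concave side toward -z like a back surface is convex toward it)
sphere_cap_cloud <- function(radius = 200, extent = 60, step = 2.5,
                             center_z = 300) {
  g <- expand.grid(x = seq(-extent, extent, step),
                   y = seq(-extent, extent, step))
  z <- center_z - sqrt(radius^2 - g$x^2 - g$y^2)
  point_cloud(cbind(g$x, g$y, z))
}

# smooth curved height field that pins all six rigid degrees of freedom
wavy_surface <- function(x, y) {
  0.004 * x^2 + 0.006 * y^2 + 8 * sin(x / 40) * cos(y / 35) + 500
}

wavy_cloud <- function(xs = seq(-100, 100, 4), ys = seq(-80, 80, 4),
                       normal_radius = 15) {
  g <- expand.grid(x = xs, y = ys)
  estimate_normals_and_curvature(
    point_cloud(cbind(g$x, g$y, wavy_surface(g$x, g$y))), normal_radius)
}

# reduced-size pipeline settings used throughout the suite: coarser sampling
# pitch and the 3x3 ICP restart grid keep runs fast while leaving every
# stage and rule identical
fast_config <- function(...) {
  defaults <- list(icp = icp_config(perturbation_interval = 5),
                   compute_colormap = FALSE, keep_intermediates = FALSE)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

fast_spec <- function(...) {
  do.call(torso_spec, utils::modifyList(list(pitch = 5), list(...)))
}
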