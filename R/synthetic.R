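#' Specification of a synthetic forward-bend torso scan
#'
#' Parametric stand-in for a depth-sensor scan of a forward-bending subject:
#' a smooth convex back surface with a waist/neck width profile (so the
#' width-polynomial boundary detection has its minima), optional breech and
#' neck/occiput extensions, an optional floor plane behind the body, a
#' controllable paraspinal hump (the rib-hump asymmetry the forward-bend
#' test exposes), additive Gaussian depth noise at consumer-sensor scale,
#' and a pose perturbation. Geometry is in mm in the sensor frame (+z into
#' the scene, x craniocaudal with the breech at low x).
#'
#' The hump is an additive anisotropic Gaussian on depth, one-sided in y;
#' its amplitude is the monotone proxy for deformity severity. `curve_type`
#' `"double"` adds a second, opposite-side hump at thoracolumbar level.
#'
#' @param trunk_length back length between the breech and neck boundaries
#'   (mm, default 450).
#' @param hump_amplitude hump depth amplitude a (mm, >= 0).
#' @param hump_center optional `c(x, y)` hump centre; default mid-thoracic
#'   paraspinal, at `breech_length + 0.62 * trunk_length` (or `0.30` for
#'   `curve_type = "thoracolumbar"`) and y = 45.
#' @param hump_spread `c(sx, sy)` Gaussian spreads (mm).
#' @param curve_type one of `"single_thoracic"`, `"double"`,
#'   `"thoracolumbar"`.
#' @param include_floor,include_neck,include_breech content switches.
#' @param rot_x,rot_y,rot_z pose perturbation (degrees), applied last about
#'   the body centroid (order `Rx Ry Rz`).
#' @param noise_sd additive depth noise sigma (mm); 1.0 is consumer-grade,
#'   0.2 digitizer-grade.
#' @param pitch sampling pitch of the surface grid (mm, default 2.5).
#' @param standoff distance from the sensor to the nearest back point (mm).
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return an object of class `torso_spec`.
#' @export
torso_spec <- function(trunk_length = 450,
                       hump_amplitude = 0,
                       hump_center = NULL,
                       hump_spread = c(60, 35),
                       curve_type = c("single_thoracic", "double",
                                      "thoracolumbar"),
                       include_floor = TRUE,
                       include_neck = TRUE,
                       include_breech = TRUE,
                       rot_x = 0, rot_y = 0, rot_z = 0,
                       noise_sd = 0,
                       pitch = 2.5,
                       standoff = 900,
                       seed = 1L) {
  curve_type <- match.arg(curve_type)
  if (hump_amplitude < 0) stop("hump_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pitch <= 0) stop("pitch must be > 0")
  if (trunk_length <= 100) stop("trunk_length implausibly short")
  structure(list(trunk_length = trunk_length,
                 hump_amplitude = hump_amplitude,
                 hump_center = hump_center,
                 hump_spread = hump_spread,
                 curve_type = curve_type,
                 include_floor = include_floor,
                 include_neck = include_neck,
                 include_breech = include_breech,
                 rot_x = rot_x, rot_y = rot_y, rot_z = rot_z,
                 noise_sd = noise_sd,
                 pitch = pitch,
                 standoff = standoff,
                 seed = as.integer(seed)),
            class = "torso_spec")
}

# Half-width profile of the scan content along x: wide breech, waist minimum
# at the breech boundary, shoulders, sharp neck minimum, occiput/head blob.
# Control points scale with the trunk length; natural-spline interpolation
# keeps the profile smooth so region growing sees one surface.
torso_half_width <- function(spec) {
  bl <- if (spec$include_breech) 150 else 0
  L <- spec$trunk_length
  x_waist <- bl
  x_neck <- bl + L
  cp_x <- c(-150, 0, 70, x_waist, x_waist + 0.22 * L, x_waist + 0.51 * L,
            x_waist + 0.73 * L, x_neck - 0.12 * L, x_neck,
            x_neck + 50, x_neck + 100, x_neck + 150, x_neck + 300)
  cp_w <- c(140, 140, 170, 115, 150, 170, 175, 120, 55, 80, 95, 100, 100)
  f <- stats::splinefun(cp_x, cp_w, method = "fmm")
  function(x) pmax(f(x), 20)
}

# Deterministic depth field z(x, y) of the unperturbed, noiseless surface.
torso_depth <- function(spec) {
  bl <- if (spec$include_breech) 150 else 0
  L <- spec$trunk_length
  x_lo <- 0
  x_hi <- bl + L + if (spec$include_neck) 150 else 0
  mid <- (x_lo + x_hi) / 2
  humps <- torso_humps(spec)
  function(x, y) {
    z <- spec$standoff +
      40 * ((x - mid) / ((x_hi - x_lo) / 2))^2 +   # sagittal bend
      y^2 / (2 * 180)                              # convex cross-section
    for (h in humps)
      z <- z - h$a * exp(-((x - h$xc)^2 / (2 * h$sx^2) +
                             (y - h$yc)^2 / (2 * h$sy^2)))
    z
  }
}

torso_humps <- function(spec) {
  if (spec$hump_amplitude == 0) return(list())
  bl <- if (spec$include_breech) 150 else 0
  L <- spec$trunk_length
  sx <- spec$hump_spread[1]
  sy <- spec$hump_spread[2]
  ctr <- spec$hump_center
  if (spec$curve_type == "single_thoracic") {
    if (is.null(ctr)) ctr <- c(bl + 0.62 * L, 45)
    list(list(a = spec$hump_amplitude, xc = ctr[1], yc = ctr[2],
              sx = sx, sy = sy))
  } else if (spec$curve_type == "thoracolumbar") {
    if (is.null(ctr)) ctr <- c(bl + 0.30 * L, 45)
    list(list(a = spec$hump_amplitude, xc = ctr[1], yc = ctr[2],
              sx = sx, sy = sy))
  } else {
    if (is.null(ctr)) ctr <- c(bl + 0.65 * L, 45)
    list(list(a = spec$hump_amplitude, xc = ctr[1], yc = ctr[2],
              sx = sx, sy = sy),
         list(a = 0.8 * spec$hump_amplitude, xc = bl + 0.28 * L,
              yc = -ctr[2], sx = sx, sy = sy))
  }
}

#' Generate a synthetic torso scan
#'
#' Samples the parametric surface on a y-symmetric grid at the spec's pitch
#' (so a zero-amplitude, zero-noise scan is exactly mirror symmetric about
#' y = 0), adds the floor plane 400 mm behind the deepest body point, adds
#' Gaussian depth noise, and finally applies the pose perturbation to the
#' body (the floor stays fixed, as a real floor would).
#'
#' @param spec a [torso_spec()].
#' @return a `point_cloud` (stage `P0`).
#' @export
generate_scan <- function(spec) {
  if (!inherits(spec, "torso_spec")) stop("spec must be a torso_spec")
  h <- torso_half_width(spec)
  zf <- torso_depth(spec)
  bl <- if (spec$include_breech) 150 else 0
  x_hi <- bl + spec$trunk_length + if (spec$include_neck) 150 else 0
  xs <- seq(0, x_hi, by = spec$pitch)
  ymax <- spec$pitch * floor(200 / spec$pitch)
  ys <- seq(-ymax, ymax, by = spec$pitch)
  g <- expand.grid(x = xs, y = ys)
  keep <- abs(g$y) <= h(g$x)
  g <- g[keep, ]
  body <- cbind(g$x, g$y, zf(g$x, g$y))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  if (spec$noise_sd > 0)
    body[, 3] <- body[, 3] + stats::rnorm(nrow(body), sd = spec$noise_sd)

  if (spec$rot_x != 0 || spec$rot_y != 0 || spec$rot_z != 0) {
    R <- rot_x(spec$rot_x) %*% rot_y(spec$rot_y) %*% rot_z(spec$rot_z)
    ctr <- colMeans(body)
    body <- sweep(sweep(body, 2, ctr) %*% t(R), 2, ctr, "+")
  }

  pts <- body
  if (spec$include_floor) {
    zfloor <- max(body[, 3]) + 400
    fx <- seq(-300, x_hi + 300, by = 15)
    fy <- seq(-600, 600, by = 15)
    fg <- expand.grid(x = fx, y = fy)
    fz <- rep(zfloor, nrow(fg))
    if (spec$noise_sd > 0) fz <- fz + stats::rnorm(nrow(fg), sd = spec$noise_sd)
    pts <- rbind(pts, cbind(fg$x, fg$y, fz))
  }
  point_cloud(pts, stage_tag = "P0")
}

#' Generate a synthetic screening cohort
#'
#' Draws Cobb angles from a truncated-normal severity distribution, maps
#' each to a hump amplitude through `cobb_to_amplitude` (plus optional
#' amplitude noise), generates a scan per subject and runs the full pipeline
#' on it, returning paired (Cobb, I_asym) records. The amplitude map is a
#' construction choice, not a biomechanical model; synthetic correlations
#' are construction-dependent.
#'
#' @param n number of subjects (>= 2).
#' @param cobb_to_amplitude function mapping Cobb angle (degrees) to hump
#'   amplitude (mm); default `0.12 * cobb`.
#' @param seed integer seed for the whole cohort.
#' @param config a [run_config()] used for every subject.
#' @param spec_template a [torso_spec()] providing all non-deformity
#'   parameters (pitch, noise, floor, ...).
#' @param amplitude_noise_sd sd of additive amplitude noise (mm).
#' @param cobb_mean,cobb_sd severity distribution parameters (degrees).
#' @param curve_type_probs sampling probabilities for the three curve types
#'   (single thoracic, double, thoracolumbar).
#' @return a `screening_dataset` data frame with columns `id`, `cobb`,
#'   `curve_type`, `i_asym`, `seed`.
#' @export
generate_cohort <- function(n, cobb_to_amplitude = function(cobb) 0.12 * cobb,
                            seed = 1L,
                            config = run_config(),
                            spec_template = torso_spec(),
                            amplitude_noise_sd = 0,
                            cobb_mean = 21, cobb_sd = 13,
                            curve_type_probs = c(0.48, 0.28, 0.24)) {
  if (n < 2) stop("n must be >= 2")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  cobb <- pmax(0, round(stats::rnorm(n, cobb_mean, cobb_sd)))
  types <- sample(c("single_thoracic", "double", "thoracolumbar"), n,
                  replace = TRUE, prob = curve_type_probs)
  amp <- pmax(0, cobb_to_amplitude(cobb) +
                if (amplitude_noise_sd > 0)
                  stats::rnorm(n, sd = amplitude_noise_sd) else 0)
  scan_seeds <- sample.int(2^30, n)

  i_asym <- numeric(n)
  for (i in seq_len(n)) {
    spec <- spec_template
    spec$hump_amplitude <- amp[i]
    spec$curve_type <- types[i]
    spec$hump_center <- NULL
    spec$seed <- scan_seeds[i]
    res <- run_pipeline(generate_scan(spec), config)
    i_asym[i] <- res$I_asym
  }
  out <- data.frame(id = sprintf("S%03d", seq_len(n)), cobb = cobb,
                    curve_type = types, i_asym = i_asym, seed = scan_seeds)
  class(out) <- c("screening_dataset", "data.frame")
  out
}

#' Write / read a cohort CSV
#'
#' @param data a `screening_dataset`.
#' @param path file path.
#' @return `path` invisibly for the writer; a `screening_dataset` for the
#'   reader.
#' @export
write_cohort_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cobb", "i_asym")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("cohort CSV lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$id)) stop("cohort ids must be unique")
  if (any(d$i_asym < 0) || any(d$cobb < 0))
    stop("i_asym and cobb must be non-negative")
  class(d) <- c("screening_dataset", "data.frame")
  d
}
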