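#' ICP configuration
#'
#' Parameters of the perturbation-restarted point-to-plane ICP used to fit
#' the reflected back surface to the original one. Defaults are the pipeline
#' operating point: a 50 degree normal-compatibility gate on point pairs,
#' rotational restarts from -5 to 5 degrees at 1.25 degree intervals about x
#' and y (a 9 x 9 grid), exactly 50 iterations per start, 25 mm normal
#' estimation neighborhoods, and a central 90% width restriction.
#'
#' @param normal_angle_threshold gate on the angle between paired normals
#'   (degrees).
#' @param perturbation_range half-range of the restart rotations (degrees).
#' @param perturbation_interval restart grid spacing (degrees); must divide
#'   the range.
#' @param perturbation_axes axes perturbed, subset of `c("x", "y")`.
#' @param iterations_per_start fixed iteration count per start (no early
#'   stop unless `convergence_tol` is set).
#' @param neighborhood_radius normal/curvature estimation radius r5 (mm).
#' @param width_fraction central fraction of the y-extent kept for
#'   registration.
#' @param max_correspondence_distance optional distance gate on pairs (mm);
#'   `Inf` (default) disables it — pairing is gated on normal angle only.
#' @param convergence_tol optional early-stop tolerance on the objective
#'   decrease (mm^2); `NULL` (default) runs all iterations.
#' @return an object of class `icp_config`.
#' @export
icp_config <- function(normal_angle_threshold = 50,
                       perturbation_range = 5,
                       perturbation_interval = 1.25,
                       perturbation_axes = c("x", "y"),
                       iterations_per_start = 50,
                       neighborhood_radius = 25,
                       width_fraction = 0.90,
                       max_correspondence_distance = Inf,
                       convergence_tol = NULL) {
  if (iterations_per_start < 1) stop("iterations_per_start must be >= 1")
  if (width_fraction <= 0 || width_fraction > 1)
    stop("width_fraction must be in (0, 1]")
  if (perturbation_range > 0) {
    ratio <- perturbation_range / perturbation_interval
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("perturbation_range must be divisible by perturbation_interval")
  }
  if (!all(perturbation_axes %in% c("x", "y")))
    stop("perturbation_axes must be a subset of c('x', 'y')")
  structure(list(normal_angle_threshold = normal_angle_threshold,
                 perturbation_range = perturbation_range,
                 perturbation_interval = perturbation_interval,
                 perturbation_axes = perturbation_axes,
                 iterations_per_start = as.integer(iterations_per_start),
                 neighborhood_radius = neighborhood_radius,
                 width_fraction = width_fraction,
                 max_correspondence_distance = max_correspondence_distance,
                 convergence_tol = convergence_tol),
            class = "icp_config")
}

#' Reflect a cloud across the approximate median sagittal plane
#'
#' Mirror projection with respect to the x-z plane: `y -> -y` for every point
#' and every normal y-component. Curvature radii and side flags are preserved
#' (reflection is an isometry).
#'
#' @param cloud a pose-normalized `point_cloud`.
#' @param stage_tag stage tag for the reflected cloud (default `P4r`).
#' @return the reflected `point_cloud`.
#' @export
reflect_sagittal <- function(cloud, stage_tag = "P4r") {
  out <- cloud
  out$points[, 2] <- -out$points[, 2]
  if (!is.null(out$normals)) out$normals[, 2] <- -out$normals[, 2]
  out$stage_tag <- stage_tag
  out
}

#' Restrict a cloud to the central fraction of its y-extent
#'
#' Trims `(1 - width_fraction) / 2` of the y-extent from each side; the outer
#' bands carry the largest measurement error (high incident angle) and are
#' excluded from registration.
#'
#' @param cloud a `point_cloud`.
#' @param width_fraction fraction of the y-extent kept (default 0.9).
#' @param stage_tag stage tag for the restricted cloud.
#' @return the restricted `point_cloud`.
#' @export
restrict_width <- function(cloud, width_fraction = 0.9, stage_tag = "P5") {
  if (width_fraction <= 0 || width_fraction > 1)
    stop("width_fraction must be in (0, 1]")
  y <- cloud$points[, 2]
  r <- range(y)
  trim <- (1 - width_fraction) / 2 * diff(r)
  keep <- y >= r[1] + trim & y <= r[2] - trim
  if (!any(keep)) stop("width restriction removed every point")
  subset_cloud(cloud, keep, stage_tag = stage_tag)
}

#' Point-to-plane ICP from a single initial transform
#'
#' Runs exactly `cfg$iterations_per_start` iterations from `initial`. Each
#' iteration pairs every moving point with its closest fixed point, drops
#' pairs whose normal angle (fixed normal vs the moving normal under the
#' current iterate) exceeds the gate, solves the linearized point-to-plane
#' least squares for the 6-DOF increment, and composes. The objective is the
#' mean squared point-to-plane distance over valid pairs.
#'
#' @param fixed the fixed `point_cloud`; must carry normals.
#' @param moving the moving `point_cloud`; must carry normals (for the gate).
#' @param cfg an `icp_config`.
#' @param initial initial `rigid_transform` (identity by default).
#' @return an object of class `icp_result` with `best_transform`,
#'   `objective_value` (mm^2), `iteration_objectives`, `valid_pair_count`.
#' @export
icp_point_to_plane <- function(fixed, moving, cfg = icp_config(),
                               initial = rigid_transform()) {
  if (is.null(fixed$normals)) stop("fixed cloud must carry normals")
  if (is.null(moving$normals)) stop("moving cloud must carry normals")
  if (n_points(moving) == 0L) stop("empty cloud")
  fp <- fixed$points
  fn <- fixed$normals
  mp0 <- moving$points
  mn0 <- moving$normals
  cos_gate <- cos(cfg$normal_angle_threshold * pi / 180)
  Tcur <- initial
  it_obj <- numeric(0)
  prev_obj <- Inf

  correspondences <- function(Tc) {
    mp <- sweep(mp0 %*% t(Tc$rotation), 2, Tc$translation, "+")
    mn <- mn0 %*% t(Tc$rotation)
    nn <- nn_1(fp, mp)
    ci <- nn$idx
    cosang <- rowSums(fn[ci, , drop = FALSE] * mn)
    valid <- cosang >= cos_gate
    if (is.finite(cfg$max_correspondence_distance))
      valid <- valid & nn$dist <= cfg$max_correspondence_distance
    resid <- rowSums(fn[ci, , drop = FALSE] * (mp - fp[ci, , drop = FALSE]))
    list(mp = mp, ci = ci, valid = valid, resid = resid)
  }

  for (it in seq_len(cfg$iterations_per_start)) {
    cr <- correspondences(Tcur)
    if (!any(cr$valid)) stop("registration diverged")
    v <- which(cr$valid)
    r <- cr$resid[v]
    obj <- mean(r^2)
    it_obj <- c(it_obj, obj)
    nvm <- fn[cr$ci[v], , drop = FALSE]
    pv <- cr$mp[v, , drop = FALSE]
    A <- cbind(pv[, 2] * nvm[, 3] - pv[, 3] * nvm[, 2],
               pv[, 3] * nvm[, 1] - pv[, 1] * nvm[, 3],
               pv[, 1] * nvm[, 2] - pv[, 2] * nvm[, 1],
               nvm)
    x <- tryCatch(solve(crossprod(A), crossprod(A, -r)),
                  error = function(e) {
                    s <- svd(A)
                    dinv <- ifelse(s$d > 1e-10 * s$d[1], 1 / s$d, 0)
                    s$v %*% (dinv * crossprod(s$u, -r))
                  })
    x <- as.numeric(x)
    inc <- rigid_transform(rotation_from_axis_angle(x[1:3]), x[4:6])
    Tcur <- compose_transform(inc, Tcur)
    if (!is.null(cfg$convergence_tol) &&
        abs(prev_obj - obj) < cfg$convergence_tol) break
    prev_obj <- obj
  }
  cr <- correspondences(Tcur)
  if (!any(cr$valid)) stop("registration diverged")
  final_obj <- mean(cr$resid[cr$valid]^2)
  structure(list(best_transform = Tcur,
                 objective_value = final_obj,
                 iteration_objectives = it_obj,
                 valid_pair_count = sum(cr$valid),
                 per_start_objectives = NULL),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result: objective %.4g mm^2, %d valid pairs%s>\n",
              x$objective_value, x$valid_pair_count,
              if (!is.null(x$per_start_objectives))
                sprintf(", %d starts", length(x$per_start_objectives)) else ""))
  invisible(x)
}

#' Best mirror fit over a grid of rotational restarts
#'
#' Runs [icp_point_to_plane()] from every initial orientation on the grid of
#' x/y pre-rotations (about the moving cloud centroid) defined by the config
#' and returns the start with the smallest final objective. The fitted
#' transform otherwise depends slightly on the initial orientation; the
#' restart grid removes that sensitivity. Ties break toward the lowest
#' (x-index, y-index) pair; restarts are pure and order-independent.
#'
#' @param fixed,moving as in [icp_point_to_plane()].
#' @param cfg an `icp_config`.
#' @return an `icp_result` with `per_start_objectives` (matrix, x-angles in
#'   rows) and `start_angles` attached.
#' @export
best_fit_with_perturbations <- function(fixed, moving, cfg = icp_config()) {
  angles <- if (cfg$perturbation_range > 0)
    seq(-cfg$perturbation_range, cfg$perturbation_range,
        by = cfg$perturbation_interval) else 0
  ax <- if ("x" %in% cfg$perturbation_axes) angles else 0
  ay <- if ("y" %in% cfg$perturbation_axes) angles else 0
  ctr <- centroid(moving)
  best <- NULL
  objs <- matrix(Inf, length(ax), length(ay),
                 dimnames = list(ax, ay))
  for (i in seq_along(ax)) {
    for (j in seq_along(ay)) {
      init <- rotation_about(rot_x(ax[i]) %*% rot_y(ay[j]), ctr)
      res <- tryCatch(icp_point_to_plane(fixed, moving, cfg, init),
                      error = function(e) NULL)
      if (is.null(res)) next
      objs[i, j] <- res$objective_value
      if (is.null(best) || res$objective_value < best$objective_value)
        best <- res
    }
  }
  if (is.null(best)) stop("registration diverged")
  best$per_start_objectives <- objs
  attr(best, "start_angles") <- list(x = ax, y = ay)
  best
}

#' Apply the optimal mirror fit to the full reflected cloud
#'
#' Applies the optimum rotation and translation found on the width-restricted
#' pair to the full reflected cloud, yielding the optimal reflected cloud
#' best fitted to the original back surface.
#'
#' @param P4r the full reflected `point_cloud` (stage `P4r`).
#' @param result an `icp_result`.
#' @return a `point_cloud` with stage tag `P6r`.
#' @export
make_optimal_reflection <- function(P4r, result) {
  apply_transform(P4r, result$best_transform, stage_tag = "P6r")
}

#' Dump per-start ICP objectives as CSV (diagnostics)
#'
#' @param result an `icp_result` from [best_fit_with_perturbations()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_start_objectives_csv <- function(result, path) {
  if (is.null(result$per_start_objectives))
    stop("result has no per-start objectives")
  m <- result$per_start_objectives
  d <- data.frame(angle_x = rep(as.numeric(rownames(m)), ncol(m)),
                  angle_y = rep(as.numeric(colnames(m)), each = nrow(m)),
                  objective = as.vector(m))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
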