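#' Moving-average smoothing of a point cloud
#'
#' Each output point is the centroid of the input points within
#' `window_radius` of the corresponding input point (the point itself
#' included). Reduces depth-sensor noise before segmentation; the point count
#' is unchanged.
#'
#' @param raw a `point_cloud`.
#' @param window_radius averaging radius in mm (default 5, about 2-4x the
#'   sensor point spacing).
#' @return the smoothed cloud, stage tag `P1`.
#' @export
smooth_cloud <- function(raw, window_radius = 5) {
  if (n_points(raw) == 0L) stop("empty cloud")
  if (!is.numeric(window_radius) || window_radius <= 0)
    stop("window_radius must be > 0")
  pts <- raw$points
  nb <- radius_search(pts, pts, window_radius)
  idx <- nb$idx
  idx[idx == 0L] <- NA_integer_
  cnt <- rowSums(!is.na(idx))
  out <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    v <- matrix(pts[idx, d], nrow(idx), ncol(idx))
    out[, d] <- rowSums(v, na.rm = TRUE) / cnt
  }
  point_cloud(out, stage_tag = "P1")
}

#' Smoothness-constrained region growing segmentation
#'
#' Partitions a cloud into connected smooth regions: seeds are taken in
#' ascending order of PCA surface variation, and a neighbor (over a
#' k-nearest-neighbor graph) joins a region when the angle between its normal
#' and the normal of the point it was reached from is below
#' `angle_threshold`. Every point ends up in exactly one region.
#'
#' @param cloud a `point_cloud`; normals are estimated first when absent.
#' @param angle_threshold normal-angle threshold in degrees (default 10).
#' @param k neighbor-graph size (default 10 nearest neighbors).
#' @param normal_radius radius used when normals must be estimated (mm).
#' @return an object of class `segmentation_result` with fields `regions`
#'   (list of `point_cloud`), `region_indices`, `bbox_side_sums`,
#'   `mean_depths`, `selected_index` (`NA` until a body region is selected).
#' @export
segment_regions <- function(cloud, angle_threshold = 10, k = 10,
                            normal_radius = 10) {
  n <- n_points(cloud)
  if (n == 0L) stop("empty cloud")
  if (is.null(cloud$normals) || is.null(cloud$surface_variation))
    cloud <- estimate_normals_and_curvature(cloud, radius = normal_radius,
                                            curvature = FALSE)
  normals <- cloud$normals
  k <- min(k + 1L, n)          # +1: nn2 returns the point itself first
  nbidx <- RANN::nn2(cloud$points, cloud$points, k = k, eps = 0)$nn.idx
  cos_thr <- cos(angle_threshold * pi / 180)

  labels <- integer(n)
  order_seeds <- order(cloud$surface_variation, seq_len(n))
  region <- 0L
  for (seed in order_seeds) {
    if (labels[seed] != 0L) next
    region <- region + 1L
    labels[seed] <- region
    queue <- seed
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      nbs <- nbidx[p, ]
      nbs <- nbs[labels[nbs] == 0L]
      if (length(nbs) == 0L) next
      cosang <- abs(as.numeric(normals[nbs, , drop = FALSE] %*% normals[p, ]))
      join <- nbs[cosang >= cos_thr]
      if (length(join) > 0L) {
        labels[join] <- region
        queue <- c(queue, join)
      }
    }
  }

  region_indices <- split(seq_len(n), labels)
  regions <- lapply(region_indices, function(ix) subset_cloud(cloud, ix))
  structure(list(regions = regions,
                 region_indices = region_indices,
                 labels = labels,
                 bbox_side_sums = vapply(regions, bbox_side_sum, numeric(1)),
                 mean_depths = vapply(regions, function(r)
                   mean(r$points[, 3]), numeric(1)),
                 selected_index = NA_integer_),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: %d regions (sizes %s)>\n",
              length(x$regions),
              paste(vapply(x$regions, n_points, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Select the body-sized region closest to the sensor
#'
#' Among regions whose bounding-box side-length sum exceeds `min_bbox_sum`
#' (the body-size gate, 650 mm), returns the one with minimal mean depth
#' (mean z, i.e. closest to the sensor).
#'
#' @param seg a `segmentation_result`.
#' @param min_bbox_sum gate on the sum of bounding-box side lengths (mm).
#' @return the selected region as a `point_cloud`, stage tag `P2`. The
#'   selection index is recorded in `attr(, "selected_index")`.
#' @export
select_body_region <- function(seg, min_bbox_sum = 650) {
  ok <- which(seg$bbox_side_sums > min_bbox_sum)
  if (length(ok) == 0L) stop("no body-sized region found")
  sel <- ok[which.min(seg$mean_depths[ok])]
  out <- seg$regions[[sel]]
  out$stage_tag <- "P2"
  attr(out, "selected_index") <- sel
  out
}

#' Segmentation diagnostics as JSON
#'
#' @param seg a `segmentation_result`.
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
segmentation_diagnostics_json <- function(seg, path = NULL) {
  d <- list(n_regions = length(seg$regions),
            sizes = vapply(seg$regions, n_points, integer(1)),
            bbox_side_sums = seg$bbox_side_sums,
            mean_depths = seg$mean_depths,
            selected_index = seg$selected_index)
  js <- jsonlite::toJSON(d, auto_unbox = TRUE, digits = 6)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Pose-normalize a body cloud by principal axes
#'
#' Rotates and centres the cloud so its principal axes align with the
#' coordinate axes: largest variance to x (craniocaudal), second to y
#' (mediolateral), third to z; the centroid moves to the origin, so the
#' approximate median sagittal plane becomes the x-z plane. Signs are fixed
#' deterministically: under `"anatomical"` the scene-depth direction keeps
#' pointing along +z and the wider end of the width profile (the breech side)
#' goes to lower x; under `"nearest"` each axis is oriented to agree with the
#' axis it replaces. y completes a right-handed frame in both cases.
#'
#' @param body a `point_cloud`.
#' @param sign_rule `"anatomical"` (default) or `"nearest"`.
#' @return list with `cloud` (stage tag `P3`) and `transform` (the
#'   `rigid_transform` that was applied).
#' @export
pose_normalize <- function(body, sign_rule = c("anatomical", "nearest")) {
  sign_rule <- match.arg(sign_rule)
  pts <- body$points
  if (nrow(pts) < 4L) stop("degenerate covariance")
  ctr <- colMeans(pts)
  C <- stats::cov(pts)
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values
  if (any(abs(diff(ev)) <= 1e-9 * max(abs(ev))))
    stop("degenerate covariance")
  R <- t(e$vectors)   # rows are the new axes, largest variance first

  if (sign_rule == "anatomical") {
    # keep scene depth along +z
    if (R[3, 3] < 0) R[3, ] <- -R[3, ]
    # breech (wider end of the width profile) at lower x
    xs <- as.numeric(sweep(pts, 2, ctr) %*% R[1, ])
    ys <- as.numeric(sweep(pts, 2, ctr) %*% R[2, ])
    q <- stats::quantile(xs, c(0.25, 0.75), names = FALSE)
    span <- function(v) diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))
    if (span(ys[xs >= q[2]]) > span(ys[xs <= q[1]])) R[1, ] <- -R[1, ]
  } else {
    if (R[3, 3] < 0) R[3, ] <- -R[3, ]
    if (R[1, 1] < 0) R[1, ] <- -R[1, ]
  }
  R[2, ] <- cross3(R[3, ], R[1, ])   # right-handed: y = z x x

  xf <- rigid_transform(R, as.numeric(-R %*% ctr))
  out <- apply_transform(body, xf, stage_tag = "P3")
  list(cloud = out, transform = xf)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
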