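#' Posture gate
#'
#' Capture validity check: a least-squares plane is fitted to the detected
#' body region and the tilt of its normal relative to the sensor viewing
#' axis is split into rotations about x and y. The capture passes when
#' `|rot_x| < limit_x` and `|rot_y| < limit_y` (defaults 7.5 and 15
#' degrees).
#'
#' @param limit_x,limit_y gate limits in degrees.
#' @return an object of class `posture_gate` (unmeasured until
#'   [check_posture()] fills it).
#' @export
posture_gate <- function(limit_x = 7.5, limit_y = 15) {
  structure(list(limit_x = limit_x, limit_y = limit_y,
                 rot_x = NA_real_, rot_y = NA_real_,
                 pass = NA, reason = NULL),
            class = "posture_gate")
}

#' @export
print.posture_gate <- function(x, ...) {
  if (is.na(x$pass)) {
    cat(sprintf("<posture_gate: unmeasured (limits %.1f / %.1f deg)>\n",
                x$limit_x, x$limit_y))
  } else {
    cat(sprintf("<posture_gate: rot_x %.2f deg (limit %.1f), rot_y %.2f deg (limit %.1f) — %s>\n",
                x$rot_x, x$limit_x, x$rot_y, x$limit_y,
                if (isTRUE(x$pass)) "PASS" else paste0("FAIL (", x$reason, ")")))
  }
  invisible(x)
}

#' Check the capture posture of a raw scan
#'
#' Smooths and segments the scan, selects the body region, fits a
#' least-squares plane to it and measures the plane-normal tilt about the
#' x and y axes against the gate limits. Segmentation failures fail the
#' gate with a reason rather than erroring.
#'
#' @param scan a raw `point_cloud`.
#' @param gate a [posture_gate()].
#' @param config a [run_config()] supplying the segmentation settings.
#' @return the populated `posture_gate`.
#' @export
check_posture <- function(scan, gate = posture_gate(), config = run_config()) {
  body <- tryCatch({
    sm <- smooth_cloud(scan, config$smoothing_radius)
    seg <- segment_regions(sm, config$seg_angle_threshold, k = config$seg_k,
                           normal_radius = config$seg_normal_radius)
    select_body_region(seg, config$min_bbox_sum)
  }, error = function(e) e)
  if (inherits(body, "error")) {
    gate$pass <- FALSE
    gate$reason <- paste("segmentation failed:", conditionMessage(body))
    return(gate)
  }
  pts <- body$points
  qc <- sweep(pts, 2, colMeans(pts))
  nv <- eigen(crossprod(qc), symmetric = TRUE)$vectors[, 3L]
  if (nv[3] < 0) nv <- -nv   # orient along the viewing axis
  gate$rot_x <- atan2(-nv[2], nv[3]) * 180 / pi
  gate$rot_y <- atan2(nv[1], nv[3]) * 180 / pi
  fail <- c(if (abs(gate$rot_x) >= gate$limit_x) sprintf("x rotation %.1f deg exceeds %.1f", abs(gate$rot_x), gate$limit_x),
            if (abs(gate$rot_y) >= gate$limit_y) sprintf("y rotation %.1f deg exceeds %.1f", abs(gate$rot_y), gate$limit_y))
  gate$pass <- length(fail) == 0L
  gate$reason <- if (length(fail)) paste(fail, collapse = "; ") else NULL
  gate
}
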