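#' Pipeline run configuration
#'
#' Every tunable of the scan-to-index pipeline with its operating default:
#' 5 mm smoothing window, 10 degree region-growing threshold, 650 mm
#' body-size gate, 3 mm projection pixels, 10th-order width polynomial,
#' 90% width restriction, the ICP restart settings (50 degree gate, +-5
#' degrees at 1.25 degree intervals, 50 iterations, r5 = 25 mm), the 100 mm
#' colormap gate, 3 mm resampling grid with r8 = 25 mm, and alpha = 0.9.
#'
#' @param smoothing_radius moving-average window radius (mm).
#' @param seg_angle_threshold region-growing normal angle threshold (deg).
#' @param seg_k region-growing neighbor-graph size.
#' @param seg_normal_radius normal-estimation radius for segmentation (mm).
#' @param min_bbox_sum body-size gate on bounding-box side sums (mm).
#' @param dx_img,dy_img Stage-4 projection pixel resolution (mm).
#' @param poly_order width-polynomial order.
#' @param cranial_frac,caudal_frac boundary search windows (fractions of the
#'   x-range).
#' @param r5 normal/curvature estimation radius before registration (mm).
#' @param icp an [icp_config()].
#' @param colormap_gate Stage-7 distance gate (mm).
#' @param colormap_d_max colormap color-scale saturation (mm).
#' @param compute_colormap compute the Stage-7 colormap (display-only; can be
#'   disabled for batch runs).
#' @param dx,dy Stage-8 resampling grid spacing (mm).
#' @param r8 Stage-8 normal re-estimation radius (mm).
#' @param alpha validity parameter for the valid grid set.
#' @param gate_rot_x,gate_rot_y posture-gate limits (degrees).
#' @param keep_intermediates retain the per-stage clouds in the result.
#' @param seed seed recorded with the run (the pipeline itself is
#'   deterministic; the seed drives synthetic-data callers).
#' @return an object of class `run_config`.
#' @export
run_config <- function(smoothing_radius = 5,
                       seg_angle_threshold = 10,
                       seg_k = 10,
                       seg_normal_radius = 10,
                       min_bbox_sum = 650,
                       dx_img = 3, dy_img = 3,
                       poly_order = 10,
                       cranial_frac = 0.4, caudal_frac = 0.3,
                       r5 = 25,
                       icp = icp_config(neighborhood_radius = r5),
                       colormap_gate = 100,
                       colormap_d_max = 10,
                       compute_colormap = TRUE,
                       dx = 3, dy = 3,
                       r8 = 25,
                       alpha = 0.9,
                       gate_rot_x = 7.5, gate_rot_y = 15,
                       keep_intermediates = TRUE,
                       seed = 1L) {
  cfg <- list(smoothing_radius = smoothing_radius,
              seg_angle_threshold = seg_angle_threshold,
              seg_k = seg_k,
              seg_normal_radius = seg_normal_radius,
              min_bbox_sum = min_bbox_sum,
              dx_img = dx_img, dy_img = dy_img,
              poly_order = poly_order,
              cranial_frac = cranial_frac, caudal_frac = caudal_frac,
              r5 = r5,
              icp = icp,
              colormap_gate = colormap_gate,
              colormap_d_max = colormap_d_max,
              compute_colormap = compute_colormap,
              dx = dx, dy = dy,
              r8 = r8,
              alpha = alpha,
              gate_rot_x = gate_rot_x, gate_rot_y = gate_rot_y,
              keep_intermediates = keep_intermediates,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (lossless JSON round-trip)
#'
#' @param cfg a `run_config`.
#' @param path file path.
#' @return `path` invisibly for the writer; a `run_config` for the reader.
#' @export
write_run_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat$icp <- unclass(flat$icp)
  writeLines(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = TRUE)
  de_string <- function(x) {
    lapply(x, function(v)
      if (is.character(v) && length(v) == 1 && v %in% c("Inf", "-Inf"))
        as.numeric(v) else v)
  }
  icp_args <- de_string(raw$icp)
  raw$icp <- NULL
  raw <- de_string(raw)
  raw$icp <- do.call(icp_config, icp_args)
  cfg <- do.call(run_config, raw)
  cfg
}

#' Run the full scan-to-index pipeline
#'
#' Chains all stages: smoothing, segmentation and body selection, pose
#' normalization, back-boundary cropping, sagittal reflection and width
#' restriction, perturbation-restarted point-to-plane ICP, optional colormap
#' deviations, union-axes re-alignment, regular-grid resampling, valid-set
#' selection and the asymmetry index.
#'
#' @param raw_scan a `point_cloud` (stage `P0`).
#' @param config a [run_config()].
#' @return an object of class `asymmetry_result` with fields `I_asym` (mm),
#'   `valid_count`, `deviations` (data frame), `grid` (both resampled grids
#'   and the sets), `colormap` (or `NULL`), `icp`, `stages` (per-stage point
#'   counts, plus the clouds when `keep_intermediates`), `elapsed` (s).
#' @export
run_pipeline <- function(raw_scan, config = run_config()) {
  t0 <- proc.time()[["elapsed"]]
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  stages <- list()
  note <- function(tag, cloud) {
    stages[[tag]] <<- if (isTRUE(config$keep_intermediates)) cloud
                      else n_points(cloud)
  }
  note("P0", raw_scan)

  P1 <- stage_err("stage1-smoothing", smooth_cloud(raw_scan, config$smoothing_radius))
  note("P1", P1)

  seg <- stage_err("stage2-segmentation",
                   segment_regions(P1, config$seg_angle_threshold,
                                   k = config$seg_k,
                                   normal_radius = config$seg_normal_radius))
  P2 <- stage_err("stage2-selection",
                  select_body_region(seg, config$min_bbox_sum))
  note("P2", P2)

  pn <- stage_err("stage3-pose", pose_normalize(P2))
  P3 <- pn$cloud
  note("P3", P3)

  img <- stage_err("stage4-projection",
                   project_to_binary(P3, config$dx_img, config$dy_img))
  prof <- fit_width_polynomial(width_function(img), config$poly_order)
  bounds <- stage_err("stage4-boundaries",
                      find_back_boundaries(prof, config$cranial_frac,
                                           config$caudal_frac))
  crop <- stage_err("stage4-crop",
                    crop_back(P3, bounds[["x_neck"]], bounds[["x_breech"]]))
  P4 <- stage_err("stage4-normals",
                  estimate_normals_and_curvature(crop$cropped, config$r5))
  note("P4", P4)

  P4r <- reflect_sagittal(P4)
  P5 <- restrict_width(P4, config$icp$width_fraction, stage_tag = "P5")
  P5r <- restrict_width(P4r, config$icp$width_fraction, stage_tag = "P5r")
  note("P5", P5)

  fit <- stage_err("stage6-icp",
                   best_fit_with_perturbations(P5, P5r, config$icp))
  P6r <- make_optimal_reflection(P4r, fit)
  note("P6r", P6r)

  colormap <- NULL
  if (isTRUE(config$compute_colormap))
    colormap <- stage_err("stage7-colormap",
                          colormap_deviations(P4, P6r, config$colormap_gate))

  al <- stage_err("stage8-align", align_union_axes(P4, P6r))
  note("P7", al$P7)
  rs8 <- stage_err("stage8-resample",
                   resample_on_grid(al$P7, config$dx, config$dy))
  rs8r <- stage_err("stage8-resample",
                    resample_on_grid(al$P7r, config$dx, config$dy))
  sets <- stage_err("stage8-valid",
                    effective_and_valid_sets(rs8, rs8r, config$alpha))
  dev <- stage_err("stage8-deviations",
                   grid_deviations(rs8, rs8r, sets, config$r8))
  I_asym <- asymmetry_index(dev)

  structure(list(I_asym = I_asym,
                 valid_count = nrow(dev),
                 deviations = dev,
                 grid = list(P8 = rs8, P8r = rs8r, sets = sets),
                 colormap = colormap,
                 icp = fit,
                 boundaries = bounds,
                 stages = stages,
                 config = config,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("<asymmetry_result: I_asym = %.3f mm over %d valid grid points (%.1f s)>\n",
              x$I_asym, x$valid_count, x$elapsed))
  invisible(x)
}

#' Serialize an asymmetry result to JSON
#'
#' Versioned schema with the index, the valid-node count, the detected
#' boundaries, per-stage point counts and the registration objective.
#'
#' @param result an `asymmetry_result`.
#' @param path optional file to write.
#' @return JSON string, invisibly when written to file.
#' @export
asymmetry_result_json <- function(result, path = NULL) {
  counts <- lapply(result$stages, function(s)
    if (inherits(s, "point_cloud")) n_points(s) else s)
  d <- list(schema = "backsym/result/v1",
            i_asym_mm = result$I_asym,
            valid_grid_points = result$valid_count,
            x_neck = result$boundaries[["x_neck"]],
            x_breech = result$boundaries[["x_breech"]],
            icp_objective_mm2 = result$icp$objective_value,
            stage_point_counts = counts,
            elapsed_s = result$elapsed)
  js <- jsonlite::toJSON(d, auto_unbox = TRUE, digits = 10)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export grid deviations as CSV
#'
#' @param result an `asymmetry_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deviations_csv <- function(result, path) {
  utils::write.csv(result$deviations, path, row.names = FALSE)
  invisible(path)
}
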