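#' Construct a point cloud
#'
#' The universal carrier for every stage of the asymmetry pipeline. Coordinates
#' are in millimetres in the sensor frame: the sensor sits at the origin with
#' +z pointing into the scene (depth increases with z); after pose
#' normalization +x is craniocaudal and +y mediolateral.
#'
#' @param points numeric matrix (n x 3) of coordinates in mm.
#' @param normals optional numeric matrix (n x 3) of unit normals.
#' @param curvature_radii optional numeric vector of per-point radii of
#'   curvature (mm); entries for planar points may be `Inf` or `NA` and are
#'   flagged through `planar`.
#' @param planar optional logical vector; `TRUE` where the local surface is
#'   treated as a plane (infinite radius of curvature).
#' @param curvature_sign optional numeric vector in {-1, +1}: the side of the
#'   surface (along the normal) on which the osculating sphere centre lies.
#' @param surface_variation optional numeric vector, the PCA surface-variation
#'   measure used to order region-growing seeds.
#' @param stage_tag label identifying the pipeline stage artifact
#'   (`"P0"` ... `"P8r"`).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, curvature_radii = NULL,
                        planar = NULL, curvature_sign = NULL,
                        surface_variation = NULL, stage_tag = "P0") {
  points <- as_coord_matrix(points)
  n <- nrow(points)
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals)
    if (nrow(normals) != n) stop("normals must have one entry per point")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) stop("normals must have unit length")
  }
  if (!is.null(curvature_radii)) {
    curvature_radii <- as.numeric(curvature_radii)
    if (length(curvature_radii) != n)
      stop("curvature_radii must have one entry per point")
    if (is.null(planar)) planar <- !is.finite(curvature_radii)
    bad <- !planar & (!is.finite(curvature_radii) | curvature_radii <= 0)
    if (any(bad)) stop("curvature radii must be positive for non-planar points")
  }
  if (!is.null(planar)) {
    planar <- as.logical(planar)
    if (length(planar) != n) stop("planar must have one entry per point")
  }
  structure(list(points = points, normals = normals,
                 curvature_radii = curvature_radii, planar = planar,
                 curvature_sign = curvature_sign,
                 surface_variation = surface_variation,
                 stage_tag = stage_tag),
            class = "point_cloud")
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop("expected 3 columns of coordinates")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud %s: %d points%s%s>\n", x$stage_tag, n_points(x),
              if (!is.null(x$normals)) ", normals" else "",
              if (!is.null(x$curvature_radii)) ", curvature" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by index
#'
#' Keeps per-point attributes (normals, curvature, flags) aligned.
#'
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index into the points.
#' @param stage_tag optional new stage tag.
#' @return a `point_cloud`.
#' @export
subset_cloud <- function(cloud, idx, stage_tag = cloud$stage_tag) {
  pick <- function(a) {
    if (is.null(a)) return(NULL)
    if (is.matrix(a)) a[idx, , drop = FALSE] else a[idx]
  }
  structure(list(points = cloud$points[idx, , drop = FALSE],
                 normals = pick(cloud$normals),
                 curvature_radii = pick(cloud$curvature_radii),
                 planar = pick(cloud$planar),
                 curvature_sign = pick(cloud$curvature_sign),
                 surface_variation = pick(cloud$surface_variation),
                 stage_tag = stage_tag),
            class = "point_cloud")
}

#' Axis-aligned bounding-box side-length sum
#'
#' Sum of the three side lengths of the axis-aligned bounding box in the
#' current frame; the body-size gate compares this against 650 mm.
#'
#' @param cloud a `point_cloud`.
#' @return numeric, mm.
#' @export
bbox_side_sum <- function(cloud) {
  r <- apply(cloud$points, 2, range)
  sum(r[2, ] - r[1, ])
}

#' Centroid of a point cloud
#' @param cloud a `point_cloud`.
#' @return length-3 numeric (mm).
#' @export
centroid <- function(cloud) colMeans(cloud$points)
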