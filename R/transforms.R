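#' Rigid transform
#'
#' A proper rigid motion p -> R p + t with R a 3x3 rotation (det +1,
#' orthonormal) and t a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop("rigid_transform needs a 3x3 rotation and a 3-vector translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform: rotation %.3f deg, |t| = %.3f mm>\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform "apply b first, then a".
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  R <- a$rotation %*% b$rotation
  # re-orthonormalize to keep long compositions closed over the type
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param xf a `rigid_transform`.
#' @return a `rigid_transform`.
#' @export
invert_transform <- function(xf) {
  rigid_transform(t(xf$rotation), as.numeric(-t(xf$rotation) %*% xf$translation))
}

#' Apply a rigid transform to a point cloud
#'
#' Points map to `R p + t`; normals map to `R n`; radii of curvature and
#' planar/side flags are unchanged (rigid motions preserve curvature).
#'
#' @param cloud a `point_cloud`.
#' @param xf a `rigid_transform`.
#' @param stage_tag optional stage tag override; preserved by default.
#' @return a `point_cloud`.
#' @export
apply_transform <- function(cloud, xf, stage_tag = cloud$stage_tag) {
  out <- cloud
  out$points <- sweep(cloud$points %*% t(xf$rotation), 2, xf$translation, "+")
  if (!is.null(cloud$normals)) out$normals <- cloud$normals %*% t(xf$rotation)
  out$stage_tag <- stage_tag
  out
}

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# Rodrigues' formula: rotation by |w| radians about axis w.
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation about a fixed centre as a rigid transform
#'
#' @param R 3x3 rotation matrix.
#' @param center point left fixed by the motion.
#' @return a `rigid_transform` equal to rotation about `center`.
#' @export
rotation_about <- function(R, center) {
  center <- as.numeric(center)
  rigid_transform(R, center - as.numeric(R %*% center))
}
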