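#' Triangulate a cloud over its xy projection
#'
#' Delaunay triangulation of the xy-projected points; triangles with a 3D
#' edge longer than `edge_factor` times the median nearest-neighbor spacing
#' are discarded so holes and concavities are not bridged.
#'
#' @param cloud a `point_cloud`.
#' @param edge_factor long-edge rejection factor (default 4).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3 vertex
#'   indices).
#' @export
triangulate_xy <- function(cloud, edge_factor = 4) {
  pts <- cloud$points
  if (nrow(pts) < 3L) stop("need at least 3 points to triangulate")
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  if (is.null(tri) || nrow(tri) == 0L) stop("triangulation failed")
  spacing <- stats::median(RANN::nn2(pts[, 1:2], pts[, 1:2], k = 2)$nn.dists[, 2])
  e1 <- sqrt(rowSums((pts[tri[, 1], ] - pts[tri[, 2], ])^2))
  e2 <- sqrt(rowSums((pts[tri[, 2], ] - pts[tri[, 3], ])^2))
  e3 <- sqrt(rowSums((pts[tri[, 3], ] - pts[tri[, 1], ])^2))
  keep <- pmax(e1, e2, e3) <= edge_factor * spacing
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L) stop("triangulation failed")
  list(vertices = pts, triangles = tri)
}

#' Colormap deviations between the back and its fitted mirror image
#'
#' Triangulates the fitted reflected cloud and measures, for every point of
#' the original back surface, the unsigned distance along its normal ray to
#' the first mesh intersection. Distances beyond `gate` are dropped (`NA`).
#' These distances drive the deviation colormap; the asymmetry index itself
#' is computed on the Stage-8 grid instead.
#'
#' @param P4 the back `point_cloud` with normals.
#' @param P6r the fitted reflected `point_cloud` (stage `P6r`).
#' @param gate distance gate in mm (default 100).
#' @param candidate_k number of nearest mesh triangles tested per ray.
#' @return an object of class `colormap_result` with fields `mesh`,
#'   `distances` (mm, `NA` where gated or missed), `signed` (signed ray
#'   parameter of the chosen hit) and `gate`.
#' @export
colormap_deviations <- function(P4, P6r, gate = 100, candidate_k = 60) {
  if (is.null(P4$normals)) stop("P4 must carry normals")
  mesh <- triangulate_xy(P6r)
  tri <- mesh$triangles
  vx <- mesh$vertices
  cent <- (vx[tri[, 1], 1:2] + vx[tri[, 2], 1:2] + vx[tri[, 3], 1:2]) / 3
  k <- min(candidate_k, nrow(tri))
  cand <- RANN::nn2(cent, P4$points[, 1:2], k = k)$nn.idx

  n <- n_points(P4)
  d <- rep(NA_real_, n)
  sgn <- rep(NA_real_, n)
  o <- P4$points
  dir <- P4$normals
  # Moller-Trumbore across the candidate triangles of all points at once
  ti <- as.vector(cand)
  pi_ <- rep(seq_len(n), times = k)
  v0 <- vx[tri[ti, 1], , drop = FALSE]
  e1 <- vx[tri[ti, 2], , drop = FALSE] - v0
  e2 <- vx[tri[ti, 3], , drop = FALSE] - v0
  ov <- o[pi_, , drop = FALSE]
  dv <- dir[pi_, , drop = FALSE]
  pvec <- cbind(dv[, 2] * e2[, 3] - dv[, 3] * e2[, 2],
                dv[, 3] * e2[, 1] - dv[, 1] * e2[, 3],
                dv[, 1] * e2[, 2] - dv[, 2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- ov - v0
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
                tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
                tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  v <- rowSums(dv * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 &
    abs(tt) <= gate
  if (any(hit)) {
    hp <- pi_[hit]
    ht <- tt[hit]
    ord <- order(hp, abs(ht))
    hp <- hp[ord]; ht <- ht[ord]
    first <- !duplicated(hp)
    d[hp[first]] <- abs(ht[first])
    sgn[hp[first]] <- ht[first]
  }
  structure(list(mesh = mesh, distances = d, signed = sgn, gate = gate),
            class = "colormap_result")
}

#' @export
print.colormap_result <- function(x, ...) {
  cat(sprintf("<colormap_result: %d/%d points with deviations, gate %.0f mm>\n",
              sum(!is.na(x$distances)), length(x$distances), x$gate))
  invisible(x)
}

#' Write the deviation colormap as a PLY with per-vertex scalar and color
#'
#' Linear color scale saturating at `d_max`; deeper color means larger
#' deviation. Gated points are written with the sentinel scalar -1 and grey
#' color.
#'
#' @param P4 the back `point_cloud` the deviations live on.
#' @param colormap a `colormap_result`.
#' @param path output PLY path.
#' @param d_max color-scale saturation in mm (default 10).
#' @return `path`, invisibly.
#' @export
write_colormap_ply <- function(P4, colormap, path, d_max = 10) {
  d <- colormap$distances
  f <- pmin(1, d / d_max)
  col <- grDevices::colorRamp(c("white", "red"))(ifelse(is.na(f), 0, f))
  col[is.na(d), ] <- 128
  n <- n_points(P4)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "property double quality",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  q <- ifelse(is.na(d), -1, d)
  body <- paste(formatC(P4$points[, 1], format = "g", digits = 17),
                formatC(P4$points[, 2], format = "g", digits = 17),
                formatC(P4$points[, 3], format = "g", digits = 17),
                formatC(q, format = "g", digits = 17),
                round(col[, 1]), round(col[, 2]), round(col[, 3]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Re-align a cloud pair on the principal axes of their union
#'
#' One rigid transform, computed from the centroid and principal axes of the
#' union of the back and its fitted mirror image, applied identically to
#' both: the xy plane becomes the frontal plane and x the craniocaudal axis.
#' Axis signs are chosen nearest to the incoming axes (the pair is already
#' approximately pose-normalized), so the relative pose of the two clouds is
#' untouched.
#'
#' @param P4 the back `point_cloud`.
#' @param P6r the fitted reflected `point_cloud`.
#' @return list with `P7`, `P7r` (transformed clouds) and `transform`.
#' @export
align_union_axes <- function(P4, P6r) {
  union_pts <- rbind(P4$points, P6r$points)
  un <- point_cloud(union_pts)
  pn <- pose_normalize(un, sign_rule = "nearest")
  list(P7 = apply_transform(P4, pn$transform, stage_tag = "P7"),
       P7r = apply_transform(P6r, pn$transform, stage_tag = "P7r"),
       transform = pn$transform)
}

#' Resample a cloud on a regular xy grid through local spherical patches
#'
#' For each grid node, the cloud point whose xy projection is nearest to the
#' node provides a local surface patch: the sphere with that point's radius
#' of curvature tangent at it (a plane when the point is planar-flagged).
#' The node's resampled point is the intersection of the vertical line
#' through the node with the patch, taking the intersection nearer the
#' through-point. A node is effective only when the nearest projected point
#' lies within `sqrt(dx^2 + dy^2)` of the node and an intersection exists.
#'
#' @param cloud a `point_cloud` with normals and curvature (stage `P7`/`P7r`).
#' @param dx,dy grid spacing in mm (default 3).
#' @param grid_range optional list with integer vectors `l` and `m` defining
#'   the node set; defaults to the node range covered by the cloud.
#' @return an object of class `resampled_grid` with fields `l`, `m` (node
#'   indices), `points` (resampled coordinates, `NA` rows where ineffective),
#'   `effective`, `dx`, `dy`.
#' @export
resample_on_grid <- function(cloud, dx = 3, dy = 3, grid_range = NULL) {
  if (is.null(cloud$normals) || is.null(cloud$curvature_radii))
    stop("cloud must carry normals and curvature radii")
  pts <- cloud$points
  if (is.null(grid_range)) {
    l_seq <- ceiling(min(pts[, 1]) / dx):floor(max(pts[, 1]) / dx)
    m_seq <- ceiling(min(pts[, 2]) / dy):floor(max(pts[, 2]) / dy)
  } else {
    l_seq <- grid_range$l
    m_seq <- grid_range$m
  }
  nodes <- cbind(rep(l_seq, times = length(m_seq)) * dx,
                 rep(m_seq, each = length(l_seq)) * dy)
  l <- rep(l_seq, times = length(m_seq))
  m <- rep(m_seq, each = length(l_seq))

  nn <- nn_1(pts[, 1:2, drop = FALSE], nodes)
  eff <- nn$dist <= sqrt(dx^2 + dy^2)
  j <- nn$idx
  p <- pts[j, , drop = FALSE]
  nrm <- cloud$normals[j, , drop = FALSE]
  rho <- cloud$curvature_radii[j]
  planar <- if (!is.null(cloud$planar)) cloud$planar[j] else !is.finite(rho)
  csgn <- if (!is.null(cloud$curvature_sign)) cloud$curvature_sign[j]
          else rep(1, length(j))
  csgn[is.na(csgn)] <- 1

  z <- rep(NA_real_, nrow(nodes))
  # planar patch: n . (q - p) = 0 along the vertical line
  pl <- eff & planar
  nz_ok <- abs(nrm[, 3]) > 1e-8
  pl_ok <- pl & nz_ok
  z[pl_ok] <- p[pl_ok, 3] -
    (nrm[pl_ok, 1] * (nodes[pl_ok, 1] - p[pl_ok, 1]) +
       nrm[pl_ok, 2] * (nodes[pl_ok, 2] - p[pl_ok, 2])) / nrm[pl_ok, 3]
  # spherical patch: centre p + s * rho * n, radius rho
  sp <- eff & !planar
  cx <- p[, 1] + csgn * rho * nrm[, 1]
  cy <- p[, 2] + csgn * rho * nrm[, 2]
  cz <- p[, 3] + csgn * rho * nrm[, 3]
  disc <- rho^2 - (nodes[, 1] - cx)^2 - (nodes[, 2] - cy)^2
  sp_ok <- sp & disc >= 0
  root <- sqrt(pmax(disc, 0))
  zhi <- cz + root
  zlo <- cz - root
  z[sp_ok] <- ifelse(abs(zhi - p[, 3]) <= abs(zlo - p[, 3]), zhi, zlo)[sp_ok]

  eff <- eff & !is.na(z)
  out_pts <- cbind(nodes[, 1], nodes[, 2], z)
  out_pts[!eff, ] <- NA_real_
  structure(list(l = l, m = m, points = out_pts, effective = eff,
                 dx = dx, dy = dy),
            class = "resampled_grid")
}

#' @export
print.resampled_grid <- function(x, ...) {
  cat(sprintf("<resampled_grid: %d nodes, %d effective, spacing %.3g x %.3g mm>\n",
              length(x$l), sum(x$effective), x$dx, x$dy))
  invisible(x)
}

#' Effective and valid grid point sets
#'
#' A node is effective when both resampled clouds are effective there
#' (set G_E). Within each grid column l, with `M_min(l)` and `M_max(l)` the
#' extreme m indices of G_E and `W(l)` their difference, a node is valid
#' (set G_v) when
#' `M_min(l) + 0.5 (1 - alpha) W(l) <= m <= M_max(l) - 0.5 (1 - alpha) W(l)`:
#' the band of relative width `alpha` around the median sagittal plane,
#' excluding the high-incident-angle boundary. `alpha = 1` keeps all of G_E.
#'
#' @param rs8,rs8r `resampled_grid` objects for the back and its mirror
#'   image; must share spacing.
#' @param alpha validity parameter in `[0, 1]` (operating default 0.9).
#' @return list with data frame `nodes` (columns `l`, `m`, row indices into
#'   both grids, logical `valid`), and counts `n_effective`, `n_valid`.
#' @export
effective_and_valid_sets <- function(rs8, rs8r, alpha = 0.9) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (rs8$dx != rs8r$dx || rs8$dy != rs8r$dy)
    stop("grids must share spacing")
  key8 <- paste(rs8$l, rs8$m)
  key8r <- paste(rs8r$l, rs8r$m)
  i8 <- which(rs8$effective)
  match8r <- match(key8[i8], key8r)
  ok <- !is.na(match8r) & rs8r$effective[match8r]
  i8 <- i8[ok]
  i8r <- match8r[ok]
  if (length(i8) == 0L) stop("no valid grid points")
  l <- rs8$l[i8]
  m <- rs8$m[i8]

  valid <- logical(length(i8))
  for (lv in unique(l)) {
    sel <- l == lv
    mm <- m[sel]
    mmin <- min(mm); mmax <- max(mm)
    w <- mmax - mmin
    lo <- mmin + 0.5 * (1 - alpha) * w
    hi <- mmax - 0.5 * (1 - alpha) * w
    valid[sel] <- mm >= lo & mm <= hi
  }
  if (!any(valid)) stop("no valid grid points")
  list(nodes = data.frame(l = l, m = m, i8 = i8, i8r = i8r, valid = valid),
       n_effective = length(i8), n_valid = sum(valid))
}

#' Per-node deviations between the resampled back and its mirror image
#'
#' Normals are re-estimated at the valid nodes by PCA over the resampled
#' neighborhood (radius `r8`) of the back grid; the deviation at a node is
#' the unsigned point-to-plane distance from the mirror-image resampled
#' point to the plane through the back resampled point with that normal.
#' Nodes with fewer than 3 resampled neighbors are dropped with a warning.
#'
#' @param rs8,rs8r `resampled_grid` objects.
#' @param sets output of [effective_and_valid_sets()].
#' @param r8 normal re-estimation radius in mm (default 25).
#' @return data frame with columns `l`, `m`, `x`, `y`, `d` (mm) for the
#'   valid nodes that survived.
#' @export
grid_deviations <- function(rs8, rs8r, sets, r8 = 25) {
  nodes <- sets$nodes[sets$nodes$valid, , drop = FALSE]
  if (nrow(nodes) == 0L) stop("no valid grid points")
  eff8 <- which(rs8$effective)
  base <- rs8$points[eff8, , drop = FALSE]
  nb <- radius_search(base, rs8$points[nodes$i8, , drop = FALSE], r8)
  p8 <- rs8$points[nodes$i8, , drop = FALSE]
  p8r <- rs8r$points[nodes$i8r, , drop = FALSE]
  n <- nrow(nodes)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ids <- nb$idx[i, ]
    ids <- ids[ids > 0L]
    if (length(ids) < 3L) next
    q <- base[ids, , drop = FALSE]
    qc <- sweep(q, 2, colMeans(q))
    nv <- eigen(crossprod(qc), symmetric = TRUE)$vectors[, 3L]
    d[i] <- abs(sum(nv * (p8r[i, ] - p8[i, ])))
  }
  dropped <- is.na(d)
  if (any(dropped))
    warning(sprintf("%d valid nodes dropped (fewer than 3 neighbors for normal estimation)",
                    sum(dropped)))
  data.frame(l = nodes$l[!dropped], m = nodes$m[!dropped],
             x = p8[!dropped, 1], y = p8[!dropped, 2], d = d[!dropped])
}

#' Asymmetry index
#'
#' The arithmetic mean of the valid-node deviations, in mm. Zero for a back
#' surface exactly symmetric about its median sagittal plane; it grows as
#' the shape departs from mirror symmetry.
#'
#' @param deviations numeric vector of deviations (mm), or the data frame
#'   from [grid_deviations()].
#' @return mean deviation in mm.
#' @export
asymmetry_index <- function(deviations) {
  d <- if (is.data.frame(deviations)) deviations$d else as.numeric(deviations)
  if (length(d) == 0L || any(is.na(d))) stop("no valid grid points")
  mean(d)
}
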