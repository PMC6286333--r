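#' @importFrom RANN nn2
NULL

# Exact fixed-radius neighbor search on a k-d tree. RANN returns at most k
# matches; k is grown until no query row saturates, so results are exact.
# Returns a list(idx = integer matrix padded with 0, dist = matrix padded Inf).
radius_search <- function(target, query, radius, k0 = 32L) {
  nt <- nrow(target)
  k <- min(nt, max(2L, k0))
  repeat {
    res <- RANN::nn2(target, query, k = k, searchtype = "radius",
                     radius = radius, eps = 0)
    if (k == nt || !any(res$nn.idx[, k] > 0L)) break
    k <- min(nt, k * 2L)
  }
  res$nn.dists[res$nn.idx == 0L] <- Inf
  list(idx = res$nn.idx, dist = res$nn.dists)
}

nn_1 <- function(target, query) {
  res <- RANN::nn2(target, query, k = 1L, eps = 0)
  list(idx = res$nn.idx[, 1L], dist = res$nn.dists[, 1L])
}

#' Fixed-radius neighborhood of a point
#'
#' Exact Euclidean radius query against a cloud; the returned member indices
#' are sorted ascending so the result is deterministic.
#'
#' @param cloud a `point_cloud`.
#' @param center length-3 numeric, query centre (mm).
#' @param radius search radius in mm (> 0).
#' @return an object of class `neighborhood` with fields `center`, `radius`,
#'   `member_indices`.
#' @export
neighbors_within <- function(cloud, center, radius) {
  if (n_points(cloud) == 0L) stop("empty cloud")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  res <- radius_search(cloud$points, matrix(as.numeric(center), 1, 3), radius)
  idx <- sort(res$idx[res$idx > 0L])
  structure(list(center = as.numeric(center), radius = radius,
                 member_indices = idx),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood: %d members within %.3g mm of (%.4g, %.4g, %.4g)>\n",
              length(x$member_indices), x$radius,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Estimate per-point normals and radii of curvature
#'
#' For every point, the PCA normal of the neighborhood within `radius`
#' (eigenvector of the neighborhood covariance with the smallest eigenvalue)
#' and a radius of curvature from a least-squares sphere fitted to the same
#' neighborhood. Normals are re-oriented to face the sensor
#' (`n . (0,0,1) < 0`, the z-axis pointing into the scene). A point is flagged
#' planar when the sphere fit improves the plane-fit RMS residual by less than
#' 1% or the fitted radius exceeds 1e4 mm; points with fewer than 5 neighbors
#' are flagged planar with the normal estimated from whatever neighbors exist.
#'
#' @param cloud a `point_cloud`.
#' @param radius neighborhood radius in mm (pipeline default 25 mm).
#' @param curvature if `FALSE`, skip the sphere fit (normals only; faster).
#' @return the cloud with `normals`, `curvature_radii`, `planar`,
#'   `curvature_sign` and `surface_variation` filled in.
#' @export
estimate_normals_and_curvature <- function(cloud, radius = 25, curvature = TRUE) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  pts <- cloud$points
  n <- nrow(pts)
  if (n == 0L) stop("empty cloud")
  nb <- radius_search(pts, pts, radius)
  k <- ncol(nb$idx)

  normals <- matrix(0, n, 3)
  rho <- rep(Inf, n)
  planar <- rep(TRUE, n)
  csign <- rep(NA_real_, n)
  svar <- rep(0, n)

  for (i in seq_len(n)) {
    ids <- nb$idx[i, ]
    ids <- ids[ids > 0L]
    m <- length(ids)
    if (m < 3L) {
      normals[i, ] <- c(0, 0, -1)
      next
    }
    q <- pts[ids, , drop = FALSE]
    ctr <- colMeans(q)
    qc <- sweep(q, 2, ctr)
    C <- crossprod(qc) / m
    e <- eigen(C, symmetric = TRUE)
    nv <- e$vectors[, 3L]
    ev <- pmax(e$values, 0)
    tot <- sum(ev)
    svar[i] <- if (tot > 0) ev[3L] / tot else 0
    normals[i, ] <- nv
    if (!curvature || m < 5L) next

    rms_plane <- sqrt(ev[3L])
    sf <- fit_sphere(qc)
    if (is.null(sf)) next
    improvement <- if (rms_plane > 1e-9 * radius)
      (rms_plane - sf$rms) / rms_plane else 0
    if (improvement >= 0.01 && sf$radius <= 1e4) {
      planar[i] <- FALSE
      rho[i] <- sf$radius
      # side of the surface the sphere centre lies on, along the normal
      csign[i] <- sign(sum(nv * (sf$center + ctr - pts[i, ])))
      if (csign[i] == 0) csign[i] <- 1
    }
  }

  # orient toward the sensor: negative component along the viewing axis (+z)
  flip <- normals[, 3L] > 0 |
    (normals[, 3L] == 0 & (normals[, 1L] < 0 |
                             (normals[, 1L] == 0 & normals[, 2L] < 0)))
  normals[flip, ] <- -normals[flip, ]
  csign[flip] <- -csign[flip]
  len <- sqrt(rowSums(normals^2))
  len[len == 0] <- 1
  normals <- normals / len

  out <- cloud
  out$normals <- normals
  out$curvature_radii <- rho
  out$planar <- planar
  out$curvature_sign <- csign
  out$surface_variation <- svar
  out
}

# Algebraic least-squares sphere through centred neighborhood coordinates.
# Returns centre (in the centred frame), radius and RMS residual, or NULL when
# the system is numerically singular (exact plane).
fit_sphere <- function(qc) {
  A <- cbind(2 * qc, 1)
  b <- rowSums(qc^2)
  sol <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  r <- sqrt(r2)
  res <- sqrt(rowSums(sweep(qc, 2, ctr)^2)) - r
  list(center = ctr, radius = r, rms = sqrt(mean(res^2)))
}
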