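# brute-force Moller-Trumbore over every mesh triangle: the oracle for the
# colormap ray-casting
brute_ray_mesh <- function(origin, dir, mesh, gate) {
  best <- NA_real_
  for (t in seq_len(nrow(mesh$triangles))) {
    v <- mesh$vertices[mesh$triangles[t, ], ]
    e1 <- v[2, ] - v[1, ]
    e2 <- v[3, ] - v[1, ]
    p <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-12) next
    tv <- origin - v[1, ]
    u <- sum(tv * p) / det
    q <- c(tv[2] * e1[3] - tv[3] * e1[2],
           tv[3] * e1[1] - tv[1] * e1[3],
           tv[1] * e1[2] - tv[2] * e1[1])
    w <- sum(dir * q) / det
    if (u < -1e-9 || w < -1e-9 || u + w > 1 + 1e-9) next
    tt <- sum(e2 * q) / det
    if (abs(tt) > gate) next
    if (is.na(best) || abs(tt) < abs(best)) best <- tt
  }
  abs(best)
}

test_that("colormap deviations are exact on offset planes and match the ray oracle", {
  P4 <- estimate_normals_and_curvature(plane_cloud(step = 5, extent = 40), 12)
  expect_true(all(colormap_deviations(P4, P4)$distances == 0))

  P6r <- P4
  P6r$points[, 3] <- 2   # +2 mm along every (constant) normal
  cm <- colormap_deviations(P4, P6r)
  expect_equal(cm$distances, rep(2, n_points(P4)), tolerance = 1e-10)

  # random smooth fixture vs exhaustive ray-triangle intersection
  set.seed(21)
  wav <- wavy_cloud(xs = seq(-40, 40, 5), ys = seq(-40, 40, 5))
  jig <- wav
  jig$points[, 3] <- jig$points[, 3] + stats::rnorm(n_points(jig), sd = 0.5)
  cm2 <- colormap_deviations(wav, jig, gate = 100)
  probe <- seq(1, n_points(wav), by = 7)
  oracle <- vapply(probe, function(i)
    brute_ray_mesh(wav$points[i, ], wav$normals[i, ], cm2$mesh, 100),
    numeric(1))
  expect_equal(cm2$distances[probe], oracle, tolerance = 1e-9)

  expect_error(colormap_deviations(P4, point_cloud(matrix(0, 1, 3))),
               "at least 3 points")
})

test_that("union-axes alignment diagonalizes the union and preserves relative pose", {
  a <- wavy_cloud()
  b <- apply_transform(a, rigid_transform(rot_z(1), c(2, 1, 0)))
  al <- align_union_axes(a, b)
  u <- rbind(al$P7$points, al$P7r$points)
  C <- stats::cov(u)
  expect_lt(max(abs(C[upper.tri(C)])) / max(diag(C)), 1e-6)
  # same rigid map for both: cross-cloud distances unchanged
  pick <- seq(1, n_points(a), by = 97)
  d0 <- sqrt(rowSums((a$points[pick, ] - b$points[pick, ])^2))
  d1 <- sqrt(rowSums((al$P7$points[pick, ] - al$P7r$points[pick, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("grid resampling reproduces analytic planes and spheres", {
  pl <- estimate_normals_and_curvature(plane_cloud(step = 2.7, z = 7), 12)
  rs <- resample_on_grid(pl, 3, 3)
  expect_true(all(abs(rs$points[rs$effective, 3] - 7) < 1e-9))

  sp <- estimate_normals_and_curvature(sphere_cap_cloud(radius = 200,
                                                        extent = 60,
                                                        step = 2.5), 15)
  rs2 <- resample_on_grid(sp, 3, 3)
  eff <- rs2$effective
  true_z <- 300 - sqrt(200^2 - rs2$points[eff, 1]^2 - rs2$points[eff, 2]^2)
  expect_lt(max(abs(rs2$points[eff, 3] - true_z)), 0.1)

  # nodes with no nearby projected point are ineffective
  far <- resample_on_grid(pl, 3, 3,
                          grid_range = list(l = 100:102, m = 0:2))
  expect_true(all(!far$effective))
})

test_that("effective/valid sets implement the per-column alpha inequality", {
  mk <- function(l, m, eff) {
    structure(list(l = l, m = m,
                   points = cbind(l * 3, m * 3, ifelse(eff, 0, NA)),
                   effective = eff, dx = 3, dy = 3),
              class = "resampled_grid")
  }
  l <- rep(0L, 101)
  m <- 0:100
  g1 <- mk(l, m, rep(TRUE, 101))
  g2 <- mk(l, m, rep(TRUE, 101))
  s09 <- effective_and_valid_sets(g1, g2, alpha = 0.9)
  expect_identical(sort(s09$nodes$m[s09$nodes$valid]), 5:95)
  s1 <- effective_and_valid_sets(g1, g2, alpha = 1)
  expect_identical(s1$n_valid, s1$n_effective)

  # random masks vs a brute-force per-column filter
  set.seed(31)
  l2 <- rep(0:9, each = 30)
  m2 <- rep(0:29, times = 10)
  e1 <- stats::runif(300) > 0.3
  e2 <- stats::runif(300) > 0.3
  s <- effective_and_valid_sets(mk(l2, m2, e1), mk(l2, m2, e2), alpha = 0.7)
  both <- e1 & e2
  expected_valid <- integer(0)
  for (lv in 0:9) {
    ms <- m2[both & l2 == lv]
    if (length(ms) == 0) next
    w <- max(ms) - min(ms)
    ok <- ms[ms >= min(ms) + 0.15 * w & ms <= max(ms) - 0.15 * w]
    expected_valid <- c(expected_valid, 1000 * lv + ok)
  }
  got <- 1000 * s$nodes$l[s$nodes$valid] + s$nodes$m[s$nodes$valid]
  expect_setequal(got, expected_valid)

  # alpha-monotonicity of the valid count
  counts <- vapply(c(0.5, 0.7, 0.9, 1),
                   function(a) effective_and_valid_sets(mk(l2, m2, e1),
                                                       mk(l2, m2, e2),
                                                       a)$n_valid,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("grid deviations recover planted plane offsets and match a dense-normal oracle", {
  pl <- estimate_normals_and_curvature(plane_cloud(step = 2.7, extent = 60), 12)
  rs <- resample_on_grid(pl, 3, 3)
  rs_same <- rs
  sets <- effective_and_valid_sets(rs, rs_same, alpha = 1)
  d0 <- grid_deviations(rs, rs_same, sets)
  expect_true(all(d0$d == 0))

  rs_off <- rs
  rs_off$points[, 3] <- rs_off$points[, 3] + 3
  d3 <- grid_deviations(rs, rs_off, sets)
  expect_equal(d3$d, rep(3, nrow(d3)), tolerance = 1e-9)

  # curved fixture: compare against the direct formula with independently
  # estimated normals over the same resampled neighborhoods
  sp <- estimate_normals_and_curvature(sphere_cap_cloud(radius = 150,
                                                        extent = 45,
                                                        step = 2.5), 15)
  rss <- resample_on_grid(sp, 3, 3)
  rso <- rss
  rso$points[, 3] <- rso$points[, 3] + 1.5
  ss <- effective_and_valid_sets(rss, rso, alpha = 1)
  dd <- grid_deviations(rss, rso, ss, r8 = 25)
  base <- rss$points[rss$effective, ]
  oracle <- vapply(seq_len(nrow(dd)), function(i) {
    p <- c(dd$x[i], dd$y[i], NA)
    row <- which(abs(base[, 1] - dd$x[i]) < 1e-9 &
                   abs(base[, 2] - dd$y[i]) < 1e-9)[1]
    p <- base[row, ]
    nbh <- base[sqrt(colSums((t(base) - p)^2)) <= 25, , drop = FALSE]
    nv <- eigen(crossprod(sweep(nbh, 2, colMeans(nbh))),
                symmetric = TRUE)$vectors[, 3]
    abs(sum(nv * c(0, 0, 1.5)))
  }, numeric(1))
  expect_equal(dd$d, oracle, tolerance = 1e-9)
})

test_that("the asymmetry index is the exact mean of valid deviations", {
  expect_identical(asymmetry_index(c(0, 0, 0)), 0)
  expect_identical(asymmetry_index(c(1, 2, 3)), 2)
  set.seed(77)
  d <- stats::runif(1000)
  expect_equal(asymmetry_index(3.7 * d), 3.7 * asymmetry_index(d),
               tolerance = 1e-12)
  # high-precision recomputation of the mean
  expect_equal(asymmetry_index(d), sum(sort(d)) / 1000, tolerance = 1e-12)
  expect_error(asymmetry_index(numeric(0)), "no valid grid points")
})
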