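test_that("sagittal reflection is an involution that fixes symmetric clouds", {
  cl <- wavy_cloud()
  expect_equal(reflect_sagittal(reflect_sagittal(cl))$points, cl$points)
  expect_equal(as.numeric(reflect_sagittal(
    point_cloud(matrix(c(0, 5, 0), 1, 3)))$points), c(0, -5, 0))
  # cloud symmetric about y = 0: reflection equals the original as a set
  sym <- plane_cloud(step = 3, extent = 30)
  sym$points[, 2] <- sym$points[, 2] - 15
  r <- reflect_sagittal(sym)
  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))
  expect_setequal(key(r$points), key(sym$points))
  # normals have their y component negated
  wn <- wavy_cloud()
  expect_equal(reflect_sagittal(wn)$normals,
               wn$normals %*% diag(c(1, -1, 1)))
})

test_that("width restriction trims the y-extent symmetrically and exactly", {
  cl <- point_cloud(cbind(seq_len(101), seq(0, 100, 1), 0))
  expect_identical(n_points(restrict_width(cl, 1)), 101L)
  kept <- restrict_width(cl, 0.9)
  expect_true(all(kept$points[, 2] >= 5 & kept$points[, 2] <= 95))
  # brute-force oracle on a random cloud
  rc <- random_cloud(500, seed = 8)
  y <- rc$points[, 2]
  lim <- range(y) + c(1, -1) * 0.05 * diff(range(y))
  expect_identical(n_points(restrict_width(rc, 0.9)),
                   sum(y >= lim[1] & y <= lim[2]))
  expect_error(restrict_width(cl, 0), "width_fraction")
})

test_that("icp_config validates the restart grid", {
  expect_error(icp_config(perturbation_range = 5, perturbation_interval = 2),
               "divisible")
  expect_error(icp_config(iterations_per_start = 0), ">= 1")
  expect_error(icp_config(width_fraction = 1.2), "width_fraction")
  cfg <- icp_config()
  expect_equal(cfg$normal_angle_threshold, 50)
  expect_equal(cfg$perturbation_range, 5)
  expect_equal(cfg$perturbation_interval, 1.25)
  expect_equal(cfg$iterations_per_start, 50L)
  expect_equal(cfg$neighborhood_radius, 25)
  expect_equal(cfg$width_fraction, 0.9)
})

test_that("point-to-plane ICP recovers planted displacements on a curved fixture", {
  fx <- wavy_cloud()
  # identical copy from identity: zero objective, identity transform
  same <- icp_point_to_plane(fx, fx, icp_config(iterations_per_start = 5))
  expect_lt(same$objective_value, 1e-20)
  expect_lt(rotation_angle_deg(same$best_transform$rotation), 1e-8)

  # sub-mm translation recovery, same sampling
  shift <- rigid_transform(diag(3), c(0.5, 0, 0))
  res_same <- icp_point_to_plane(fx, apply_transform(fx, shift), icp_config())
  back_same <- apply_transform(apply_transform(fx, shift),
                               res_same$best_transform)
  expect_lt(sqrt(mean(rowSums((back_same$points - fx$points)^2))), 0.05)
  expect_lt(res_same$objective_value, 1e-4)

  # the harder variant: the moving cloud samples the same surface at offset
  # grid positions, so correspondences are never exact
  mv0 <- wavy_cloud(xs = seq(-98.3, 98.3, 4), ys = seq(-78.7, 78.7, 4))
  res <- icp_point_to_plane(fx, apply_transform(mv0, shift), icp_config())
  moved_back <- apply_transform(apply_transform(mv0, shift),
                                res$best_transform)
  err <- sqrt(mean(rowSums((moved_back$points - mv0$points)^2)))
  expect_lt(err, 0.05)

  # 3-degree rotation about x
  true <- rotation_about(rot_x(3), centroid(mv0))
  res2 <- icp_point_to_plane(fx, apply_transform(mv0, true), icp_config())
  err2 <- compose_transform(res2$best_transform, true)
  expect_lt(rotation_angle_deg(err2$rotation), 0.2)

  # objective is non-increasing across iterations on this smooth fixture
  expect_true(all(diff(res2$iteration_objectives) <= 1e-9))
})

test_that("perturbation restarts reduce to plain ICP on a degenerate grid and never hurt", {
  fx <- wavy_cloud()
  mv <- apply_transform(wavy_cloud(xs = seq(-99, 99, 4), ys = seq(-79, 79, 4)),
                        rigid_transform(rot_z(1), c(1, 0, 0)))
  cfg1 <- icp_config(perturbation_range = 0, iterations_per_start = 10)
  single <- icp_point_to_plane(fx, mv, cfg1)
  multi <- best_fit_with_perturbations(fx, mv, cfg1)
  expect_equal(multi$best_transform$rotation, single$best_transform$rotation)
  expect_equal(multi$objective_value, single$objective_value)
  expect_identical(dim(multi$per_start_objectives), c(1L, 1L))

  cfg9 <- icp_config(perturbation_interval = 5, iterations_per_start = 10)
  multi9 <- best_fit_with_perturbations(fx, mv, cfg9)
  unperturbed <- multi9$per_start_objectives["0", "0"]
  expect_lte(multi9$objective_value, unperturbed)
  expect_equal(min(multi9$per_start_objectives), multi9$objective_value)
})

test_that("a symmetric pair best-fits to the identity with near-zero objective", {
  sym <- estimate_normals_and_curvature(sphere_cap_cloud(
    radius = 180, extent = 70, step = 4), 20)
  refl <- reflect_sagittal(sym)
  res <- best_fit_with_perturbations(sym, refl,
                                     icp_config(perturbation_interval = 5,
                                                iterations_per_start = 15))
  expect_lt(res$objective_value, 1e-10)
  expect_lt(rotation_angle_deg(res$best_transform$rotation), 0.1)
  expect_lt(sqrt(sum(res$best_transform$translation^2)), 0.1)

  p6r <- make_optimal_reflection(refl, res)
  expect_identical(n_points(p6r), n_points(refl))
  expect_identical(p6r$stage_tag, "P6r")
  # identity result reproduces the reflected cloud
  id_res <- res
  id_res$best_transform <- rigid_transform()
  expect_equal(make_optimal_reflection(refl, id_res)$points, refl$points)
})

test_that("registration diverges loudly when the normal gate rejects all pairs", {
  fx <- wavy_cloud()
  flipped <- fx
  flipped$normals <- -flipped$normals
  expect_error(icp_point_to_plane(fx, flipped,
                                  icp_config(normal_angle_threshold = 20,
                                             iterations_per_start = 3)),
               "registration diverged")
})
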