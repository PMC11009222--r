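# Spherical-eye geometry: stereographic projection, the 5-DOF WF
# camera, the projection chain and the displacement-field resampler.

eye128 <- eye_model(200, 128)

test_that("stereographic projection matches hand-derived points", {
  # on-axis point to image centre
  p <- sphere_to_uwf_pixel(c(0, 0, 1), eye128)
  expect_equal(p$pixel[1, ], rep((128 - 1) / 2, 2))
  # (1,0,0): ray (0,0,-1)+t(1,0,1) meets z=1 at t=2 -> plane (2,0)
  s <- retialign:::uwf_pixel_scale(eye128)
  p2 <- sphere_to_uwf_pixel(c(1, 0, 0), eye128)
  expect_equal(p2$pixel[1, 1], (128 - 1) / 2 + 2 * s)
  expect_equal(p2$pixel[1, 2], (128 - 1) / 2)
  # stereographic radius identity: plane radius 2*tan(phi/2)
  for (phi in c(0.3, 0.9, 1.4)) {
    P <- c(sin(phi), 0, cos(phi))
    r_plane <- (sphere_to_uwf_pixel(P, eye128)$pixel[1, 1] - 63.5) / s
    expect_equal(r_plane, 2 * tan(phi / 2), tolerance = 1e-12)
  }
  # the projection pole is invalid
  expect_false(sphere_to_uwf_pixel(c(0, 0, -1 + 1e-9), eye128)$valid[1])
})

test_that("pixel <-> sphere round-trip is exact to 1e-9 over 1e4 points", {
  pts <- retialign:::with_seed(31, {
    u <- matrix(rnorm(3 * 12000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u[u[, 3] > -0.9, ][1:10000, ]   # exclude a pole neighbourhood
  })
  px <- sphere_to_uwf_pixel(pts, eye128)$pixel
  back <- uwf_pixel_to_sphere(px, eye128)
  expect_lt(max(abs(back - pts)), 1e-9)
  # and pixel -> sphere -> pixel
  q <- retialign:::with_seed(32, matrix(runif(2000, 0, 127), ncol = 2))
  P <- uwf_pixel_to_sphere(q, eye128)
  expect_lt(max(abs(rowSums(P^2) - 1)), 1e-12)
  q2 <- sphere_to_uwf_pixel(P, eye128)$pixel
  expect_lt(max(abs(q2 - q)), 1e-9)
  # worked inverse example: plane (2,0) -> (1,0,0)
  s <- retialign:::uwf_pixel_scale(eye128)
  expect_equal(uwf_pixel_to_sphere(c(63.5 + 2 * s, 63.5), eye128)[1, ],
               c(1, 0, 0))
})

test_that("ray-sphere far intersection matches the closed-form roots", {
  expect_equal(ray_sphere_far_intersection(c(0, 0, -0.5), c(0, 0, 0.5))[1, ],
               c(0, 0, 1))
  expect_equal(ray_sphere_far_intersection(c(0, 0, 0), c(0, 1, 0))[1, ],
               c(0, 1, 0))
  # against quadratic roots, always taking the larger parameter
  set.seed(33)
  for (rep in 1:200) {
    o <- runif(3, -0.5, 0.5); o <- o * runif(1, 0, 0.99) / max(sqrt(sum(o^2)), 1e-9)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    b <- sum(o * d); cc <- sum(o^2) - 1
    roots <- c(-b - sqrt(b^2 - cc), -b + sqrt(b^2 - cc))
    t_far <- max(roots)
    P <- ray_sphere_far_intersection(o, o + d)
    expect_lt(max(abs(P[1, ] - (o + t_far * d))), 1e-12)
    # far root exceeds the near root
    expect_gt(t_far, min(roots))
  }
  expect_error(ray_sphere_far_intersection(c(0, 0, 0.5), c(0, 0, 0.5)),
               "degenerate")
  expect_error(ray_sphere_far_intersection(c(0, 0, 1.5), c(0, 0, 0)),
               "inside")
})

test_that("f' pinning puts the WF plane centre on z = 1", {
  for (pose in list(camera_pose(), camera_pose(0.1, -0.05, -0.3, 0.3, -0.2))) {
    fp <- wf_focal_depth(pose)
    ctr <- c(pose$x, pose$y, pose$z) + pose_rotation(pose) %*% c(0, 0, fp)
    expect_equal(ctr[3], 1, tolerance = 1e-12)
  }
})

test_that("wf_pixel_to_world places centre and corners as documented", {
  K <- wf_intrinsics(55, 128)
  pose <- camera_pose(0, 0, -0.2, 0, 0)
  ctr <- wf_pixel_to_world(c(63.5, 63.5), pose, K)
  expect_equal(ctr[1, ], c(0, 0, 1), tolerance = 1e-12)  # plane-centre pinning
  fp <- wf_focal_depth(pose)
  corner <- wf_pixel_to_world(c(0, 0), pose, K)
  expect_equal(corner[1, 1], -fp * tan(55 * pi / 360), tolerance = 1e-12)
  expect_equal(corner[1, 2], -fp * tan(55 * pi / 360), tolerance = 1e-12)
  expect_error(camera_pose(0, 0, -0.2, 0, pi / 2), "pi/2")
  expect_error(camera_pose(0.8, 0.8, 0, 0, 0), "inside")
})

test_that("projection chain: on-axis centre alignment and sign conventions", {
  K <- wf_intrinsics(55, 128)
  # matched raster sizes: centre WF pixel maps to centre UWF pixel
  fld <- project_wf_grid(camera_pose(), K, eye128, c(128, 128))
  cmid <- 64  # row/col index of pixel (63, 63); centre is at 63.5
  ctr_disp <- (fld$dm[cmid, cmid] + fld$dm[cmid + 1, cmid + 1]) / 2
  expect_lt(abs(ctr_disp), 1e-6)
  expect_true(all(fld$valid))
  # theta_y > 0 moves the mapped region toward +x (larger m_p)
  fld_y <- project_wf_grid(camera_pose(theta_y = 0.3), K, eye128, c(64, 64))
  fld_0 <- project_wf_grid(camera_pose(), K, eye128, c(64, 64))
  expect_gt(mean(fld_y$dm), mean(fld_0$dm))
  # lateral camera translation shifts the region the same way
  fld_x <- project_wf_grid(camera_pose(x = 0.1), K, eye128, c(64, 64))
  expect_gt(mean(fld_x$dm), mean(fld_0$dm))
})

test_that("projection chain is continuous in each pose parameter", {
  K <- wf_intrinsics(55, 32)
  base <- c(0.02, -0.03, -0.2, 0.2, -0.1)
  f0 <- project_wf_grid(retialign:::pose_from_vector(base), K, eye128,
                        c(32, 32))
  for (j in 1:5) {
    for (h in c(1e-4, 1e-3)) {
      v <- base; v[j] <- v[j] + h
      f1 <- project_wf_grid(retialign:::pose_from_vector(v), K, eye128,
                            c(32, 32))
      delta <- mean(abs(f1$dm - f0$dm), na.rm = TRUE) +
        mean(abs(f1$dn - f0$dn), na.rm = TRUE)
      # displacement change shrinks with the perturbation (no jumps)
      expect_lt(delta, 2000 * h)
    }
  }
})

test_that("resample_with_field: identity, shift, and phantom consistency", {
  set.seed(34)
  img <- matrix(runif(64 * 64), 64)
  zero <- structure(list(dm = matrix(0, 64, 64), dn = matrix(0, 64, 64),
                         valid = matrix(TRUE, 64, 64)),
                    class = "warp_field")
  expect_identical(resample_with_field(img, zero), img)
  sh <- zero; sh$dm <- matrix(5, 64, 64)
  out <- resample_with_field(img, sh)
  expect_equal(out[, 1:59], img[, 6:64])
  # chain consistency at the true phantom pose (standard test resolution)
  sc <- standard_scene()
  fl <- sc$fields[[1]]
  rs <- resample_with_field(sc$uwf_vm, fl$warp)
  expect_gt(dice(rs, fl$vm, fl$warp$valid), 0.9)
})

test_that("forward and inverse chains invert each other", {
  K <- wf_intrinsics(55, 256)
  eye <- eye_model(200, 512)
  pose <- camera_pose(0.05, -0.02, -0.25, 0.3, -0.15)
  p <- retialign:::with_seed(35, matrix(runif(400, 20, 235), ncol = 2))
  fwd <- wf_pixel_to_uwf_pixel(p, pose, K, eye)
  back <- uwf_pixel_to_wf_pixel(fwd$pixel[fwd$valid, ], pose, K, eye)
  expect_lt(max(abs(back$pixel - p[fwd$valid, ])), 1e-8)
})

test_that("pose serialization round-trips", {
  pose <- camera_pose(0.1, -0.2, -0.3, 0.25, -0.15)
  p2 <- camera_pose_from_json(camera_pose_to_json(pose))
  expect_equal(retialign:::pose_vector(p2), retialign:::pose_vector(pose))
})
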