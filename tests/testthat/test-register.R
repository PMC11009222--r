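# Registration orchestration: the 2D pass, the pose loop, finalization.

test_that("register_2d recovers a known affine displacement of a map", {
  sc <- standard_scene()
  uwf <- sc$uwf_vm
  # WF map = cropped, affinely displaced copy of the UWF map
  A <- rbind(c(1, 0.03, 160), c(-0.03, 1, 150))   # wf -> uwf
  g <- retialign:::grid_mn(160, 160)
  q <- cbind(g$m, g$n, 1) %*% t(A)
  wf <- matrix(retialign:::bilinear_sample(uwf, q[, 1], q[, 2]), 160, 160)
  r <- register_2d(uwf, wf, reg_config())
  expect_gt(r$dice_final, 0.8)
  # recovered transform within 0.5 px of the known affine on grid points
  probe <- as.matrix(expand.grid(m = seq(20, 140, 20), n = seq(20, 140, 20)))
  truth <- cbind(probe, 1) %*% t(A)
  err <- sqrt(rowSums((poly_apply(r$T_wf_to_uwf, probe) - truth)^2))
  expect_lt(max(err), 0.5)
})

test_that("register_2d on identical maps is near-identity; empty maps fail", {
  sc <- standard_scene()
  wf <- sc$fields[[1]]$vm
  r <- register_2d(wf, wf, reg_config())
  probe <- as.matrix(expand.grid(m = seq(20, 235, 30), n = seq(20, 235, 30)))
  dev <- sqrt(rowSums((poly_apply(r$T_wf_to_uwf, probe) - probe)^2))
  expect_lt(max(dev), 0.5)
  expect_gt(r$dice_final, 0.95)
  expect_error(register_2d(sc$uwf_vm, matrix(0, 64, 64), reg_config()),
               "insufficient matches")
})

test_that("register_2d on the phantom central field crosses 0.75 dice", {
  sc <- standard_scene()
  sr <- nominal_scale_ratio(sc$eye, sc$K, camera_pose(z = sc$cfg$camera_z))
  r <- register_2d(sc$uwf_vm, sc$fields[[1]]$vm,
                   reg_config(scale_ratio = sr))
  expect_gt(r$dice_final, 0.75)
  # the matched correspondence is physically right: median ground-truth
  # error of the surviving matches under the true camera pose is sub-pixel
  gt <- wf_pixel_to_uwf_pixel(r$matches$src, sc$fields[[1]]$pose,
                              sc$K, sc$eye)$pixel
  err <- sqrt(rowSums((r$matches$dst - gt)^2))
  expect_lt(stats::median(err[r$matches$w > 0.5]), 1)
})

test_that("optimize_pose refuses a randomized rejector", {
  sc <- small_scene()
  cfg <- pose_opt_config(reg = reg_config(rejector = ransac_config()),
                         eye = sc$eye, K = sc$K)
  expect_error(optimize_pose(sc$uwf_vm, sc$fields[[1]]$vm, cfg),
               "deterministic")
})

test_that("optimize_pose keeps the init pose when it is already optimal", {
  sc <- standard_scene()
  fl <- sc$fields[[1]]   # centre field: truth is the on-axis init
  cfg <- pose_opt_config(init_pose = fl$pose, grid_steps = NULL,
                         max_outer_iters = 20L, polish_sigmas = c(1.5, 0),
                         eye = sc$eye, K = sc$K)
  res <- optimize_pose(sc$uwf_vm, fl$vm, cfg)
  err <- pose_err(res$pose, fl$pose)
  expect_lt(err$rot, 0.02)
  expect_lt(err$pos, 0.02)
  # the reported dice never falls below the init-pose dice scored with
  # the same (full) registration model
  init_row <- res$trace[res$trace$stage == "init_full", ]
  expect_gte(res$dice_final, init_row$dice - 1e-9)
  expect_equal(res$trace$dice[nrow(res$trace)], res$dice_final)
})

test_that("optimize_pose is bit-reproducible for identical config", {
  sc <- standard_scene()
  fl <- sc$fields[[5]]
  cfg <- pose_opt_config(grid_steps = c(-0.35, 0, 0.35),
                         max_outer_iters = 25L, polish_sigmas = c(2, 0),
                         eye = sc$eye, K = sc$K)
  r1 <- optimize_pose(sc$uwf_vm, fl$vm, cfg)
  r2 <- optimize_pose(sc$uwf_vm, fl$vm, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(retialign:::pose_vector(r1$pose),
                   retialign:::pose_vector(r2$pose))
  expect_identical(r1$dice_final, r2$dice_final)
})

test_that("finalize fits a consistent chain-generated match set exactly", {
  sc <- standard_scene()
  pose <- sc$fields[[2]]$pose
  # matches generated directly by the 3D chain: src = WF points, and
  # dst such that chain(dst) are the UWF targets of chain(src)
  src <- as.matrix(expand.grid(m = seq(30, 225, 15), n = seq(30, 225, 15)))
  fin <- finalize_wf_to_uwf(pose, match_set(src, src), sc$uwf_vm,
                            sc$fields[[2]]$vm, sc$eye, sc$K)
  # polish fitted between identical point sets must be ~ identity
  uwf_pts <- wf_pixel_to_uwf_pixel(src, pose, sc$K, sc$eye)
  pp <- poly_apply(fin$T_wf_to_uwf, uwf_pts$pixel[uwf_pts$valid, ])
  expect_lt(max(abs(pp - uwf_pts$pixel[uwf_pts$valid, ])), 1e-6)
})

test_that("finalized warp lands WF fiducials on their UWF ground truth", {
  sc <- standard_scene()
  fl <- sc$fields[[6]]
  cfg <- pose_opt_config(eye = sc$eye, K = sc$K)
  res <- optimize_pose(sc$uwf_vm, fl$vm, cfg)
  fin <- finalize_wf_to_uwf(res$pose, res$matches, sc$uwf_vm, fl$vm,
                            sc$eye, sc$K)
  # corner-ish fiducials of the WF frame, pushed through the finalized
  # forward mapping (chain + polish), vs the generator's ground truth
  fid <- rbind(c(40, 40), c(215, 40), c(40, 215), c(215, 215),
               c(127.5, 127.5))
  via_fit <- poly_apply(fin$T_wf_to_uwf,
                        wf_pixel_to_uwf_pixel(fid, res$pose, sc$K,
                                              sc$eye)$pixel)
  truth <- wf_pixel_to_uwf_pixel(fid, fl$pose, sc$K, sc$eye)$pixel
  expect_lt(max(sqrt(rowSums((via_fit - truth)^2))), 1)
  # and the finalized overlay beats the 2D-only one
  sr <- nominal_scale_ratio(sc$eye, sc$K, camera_pose(z = sc$cfg$camera_z))
  r2d <- register_2d(sc$uwf_vm, fl$vm, reg_config(scale_ratio = sr))
  d2d <- retialign:::dice_2d_in_uwf(sc$uwf_vm, fl$vm, r2d$T_uwf_to_wf)$dice
  expect_gte(fin$dice_final, d2d - 1e-3)
})

test_that("on-axis finalization is scaling+translation dominated", {
  sc <- standard_scene()
  pose <- camera_pose(0, 0, -0.2, 0, 0)
  # chain-consistent matches at the on-axis pose
  src <- as.matrix(expand.grid(m = seq(40, 215, 25), n = seq(40, 215, 25)))
  prj <- wf_pixel_to_uwf_pixel(src, pose, sc$K, sc$eye)
  fit <- fit_poly_wls(src, prj$pixel)
  # quadratic terms are small relative to the linear ones near the axis
  expect_lt(max(abs(fit$M[, 3:5])) * 255,
            0.05 * max(abs(fit$M[, 1:2])))
})
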