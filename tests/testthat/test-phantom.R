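# Phantom-eye generator: tree growth, rendering, scene assembly.

test_that("vessel tree is seeded-deterministic and lives on the sphere", {
  cfg <- phantom_config(seed = 5)
  t1 <- grow_vessel_tree(cfg)
  t2 <- grow_vessel_tree(cfg)
  expect_identical(t1, t2)
  for (br in t1) {
    expect_lt(max(abs(rowSums(br$vertices^2) - 1)), 1e-9)
    expect_equal(nrow(br$vertices), length(br$width_rad))
  }
  # depth 0 -> exactly n_roots unbranched polylines
  t0 <- grow_vessel_tree(phantom_config(seed = 5,
                                        tree = list(depth = 0, n_roots = 4)))
  expect_equal(length(t0), 4)
})

test_that("UWF render obeys stereographic geometry", {
  cfg <- phantom_config(seed = 6, uwf_px = 256L)
  eye <- eye_model(cfg$uwf_fov_internal_deg, cfg$uwf_px)
  # a single vessel along the z = 0 great circle renders at plane radius 2
  ring <- lapply(seq(0, 2 * pi, length.out = 200), function(a)
    c(cos(a), sin(a), 0))
  tree <- list(list(vertices = do.call(rbind, ring),
                    width_rad = rep(0.03, 200)))
  out <- render_uwf(tree, eye, cfg)
  idx <- which(out$vm > 0.9, arr.ind = TRUE)
  s <- retialign:::uwf_pixel_scale(eye)
  r_plane <- sqrt((idx[, 2] - 1 - 127.5)^2 + (idx[, 1] - 1 - 127.5)^2) / s
  expect_lt(max(abs(r_plane - 2)), 0.05)
  # a posterior-pole point renders at the image centre
  tree2 <- list(list(vertices = rbind(c(0, 0, 1), c(0.01, 0, 0.99995)),
                     width_rad = c(0.02, 0.02)))
  out2 <- render_uwf(tree2, eye, cfg)
  ctr <- which(out2$vm == max(out2$vm), arr.ind = TRUE)
  expect_lt(max(abs(ctr[1, ] - 128.5)), 2)
})

test_that("WF render is reproducible and its correspondence is consistent", {
  sc <- small_scene()
  fl1 <- render_wf(sc$tree, sc$fields[[1]]$pose, sc$K, sc$eye, sc$cfg,
                   noise_stream = 1L)
  fl2 <- render_wf(sc$tree, sc$fields[[1]]$pose, sc$K, sc$eye, sc$cfg,
                   noise_stream = 1L)
  expect_identical(fl1$image, fl2$image)
  expect_identical(fl1$vm, fl2$vm)
  # stored correspondence equals project_wf_grid at the true pose
  ref <- project_wf_grid(sc$fields[[1]]$pose, sc$K, sc$eye,
                         dim(sc$fields[[1]]$vm))
  expect_equal(sc$fields[[1]]$warp$dm, ref$dm, tolerance = 1e-9)
  # every valid WF pixel of the default layout maps inside the UWF frame
  W <- sc$eye$uwf_image_px
  for (fl in sc$fields) {
    g <- retialign:::grid_mn(nrow(fl$vm), ncol(fl$vm))
    mp <- g$m + as.numeric(fl$warp$dm); np <- g$n + as.numeric(fl$warp$dn)
    ok <- as.numeric(fl$warp$valid) > 0
    expect_true(all(mp[ok] >= 0 & mp[ok] <= W - 1 &
                      np[ok] >= 0 & np[ok] <= W - 1))
  }
})

test_that("scene assembly: field count, raster sizes, determinism", {
  sc <- small_scene()
  expect_equal(length(sc$fields), 2)
  expect_equal(dim(sc$uwf_vm), c(256, 256))
  expect_equal(dim(sc$fields[[1]]$vm), c(128, 128))
  # centre field first, steered neighbours after
  expect_equal(unname(sc$fields[[1]]$offset), c(0, 0))
  expect_true(any(sc$fields[[2]]$offset != 0))
  # full default layout: nine fields
  expect_equal(length(standard_scene()$fields), 9)
  # device-mimicking raster sizes are honoured
  cfg_dev <- phantom_config(uwf_px = 4000L, wf_px = 768L)
  expect_equal(eye_model(cfg_dev$uwf_fov_internal_deg, cfg_dev$uwf_px)$uwf_image_px,
               4000L)
  expect_equal(wf_intrinsics(cfg_dev$wf_fov_deg, cfg_dev$wf_px)$image_px, 768L)
  # scene-level determinism
  s1 <- make_scene(phantom_config(seed = 9, n_fields = 1,
                                  uwf_px = 128L, wf_px = 64L))
  s2 <- make_scene(phantom_config(seed = 9, n_fields = 1,
                                  uwf_px = 128L, wf_px = 64L))
  expect_identical(s1$uwf_image, s2$uwf_image)
  expect_identical(s1$fields[[1]]$image, s2$fields[[1]]$image)
})
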