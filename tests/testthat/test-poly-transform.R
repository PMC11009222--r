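# Second-order polynomial transforms: lifting, application, WLS
# estimation, image warping, serialization.

test_that("poly_lift returns the monomial basis in documented order", {
  expect_equal(poly_lift(c(0, 0)), c(0, 0, 0, 0, 0, 1))
  expect_equal(poly_lift(c(2, 5)), c(2, 5, 4, 25, 10, 1))
  expect_equal(poly_lift(c(-1, 3)), c(-1, 3, 1, 9, -3, 1))
  expect_error(poly_lift(c(Inf, 0)), "non-finite")
})

test_that("poly_apply evaluates M %*% lift(p)", {
  expect_equal(poly_apply(poly_identity(), c(3, 4))[1, ], c(3, 4))
  M <- rbind(c(0, 0, 1, 0, 0, 0),   # u = m^2
             c(0, 1, 0, 0, 0, 0))   # v = n
  expect_equal(poly_apply(poly_transform(M), c(2, 5))[1, ], c(4, 5))
  Mc <- rbind(c(0, 0, 0, 0, 0, 7), c(0, 0, 0, 0, 0, -2))
  pts <- matrix(runif(10), ncol = 2)
  out <- poly_apply(poly_transform(Mc), pts)
  expect_true(all(out[, 1] == 7) && all(out[, 2] == -2))
})

test_that("WLS recovers an exact polynomial relation to 1e-8", {
  set.seed(21)
  Mstar <- rbind(c(1.2, 0.1, 1e-3, -2e-3, 5e-4, 3),
                 c(-0.05, 0.9, 2e-3, 1e-3, -1e-3, -7))
  src <- matrix(runif(40, 0, 200), ncol = 2)
  dst <- poly_apply(poly_transform(Mstar), src)
  fit <- fit_poly_wls(src, dst)
  expect_lt(max(abs(fit$M - Mstar)), 1e-8)
  # estimate/apply consistency
  expect_lt(max(abs(poly_apply(fit, src) - dst)), 1e-8)
})

test_that("affine correspondences yield vanishing quadratic columns", {
  set.seed(22)
  A <- rbind(c(0.9, 0.2, 15), c(-0.1, 1.1, -4))
  src <- matrix(runif(60, 0, 300), ncol = 2)
  dst <- cbind(src, 1) %*% t(A)
  fit <- fit_poly_wls(src, dst)
  expect_lt(max(abs(fit$M[, 3:5])), 1e-8)
  expect_lt(max(abs(fit$M[, c(1, 2, 6)] - A)), 1e-8)
})

test_that("weights behave: zero removes a pair, scaling is invariant", {
  set.seed(23)
  Mstar <- rbind(c(1, 0.05, 0, 0, 1e-3, 2), c(0, 1, 1e-3, 0, 0, -1))
  src <- matrix(runif(40, 0, 100), ncol = 2)
  dst <- poly_apply(poly_transform(Mstar), src)
  # corrupt one pair, give it zero weight
  dst_bad <- dst; dst_bad[1, ] <- dst_bad[1, ] + 50
  w <- c(0, rep(1, 19))
  fit <- fit_poly_wls(src, dst_bad, w)
  expect_lt(max(abs(fit$M - Mstar)), 1e-8)
  # positive rescaling of all weights leaves the estimate unchanged
  set.seed(24)
  w2 <- runif(20, 0.2, 1)
  dstn <- dst + rnorm(40, 0, 0.1)
  f1 <- fit_poly_wls(src, dstn, w2)
  f2 <- fit_poly_wls(src, dstn, 7.3 * w2)
  expect_lt(max(abs(f1$M - f2$M)), 1e-9)
})

test_that("degenerate designs and short inputs error", {
  src <- cbind(1:10, 2 * (1:10) + 3)   # collinear points
  dst <- src
  expect_error(fit_poly_wls(src, dst), "rank-deficient")
  expect_error(fit_poly_wls(src[1:5, ], dst[1:5, ]), "at least 6")
})

test_that("warp_image_poly is exact for identity and integer shifts", {
  set.seed(25)
  img <- matrix(runif(400), 20)
  expect_identical(warp_image_poly(img, poly_identity()), img)
  # backward translation by (+3, 0): output(p) = input(p + (3,0))
  Tsh <- poly_transform(rbind(c(1, 0, 0, 0, 0, 3), c(0, 1, 0, 0, 0, 0)))
  out <- warp_image_poly(img, Tsh)
  expect_equal(out[, 1:17], img[, 4:20])
  expect_true(all(out[, 18:20] == 0))
  # delta image moves by exactly the offset
  delta <- matrix(0, 20, 20); delta[10, 12] <- 1
  outd <- warp_image_poly(delta, Tsh)
  expect_equal(outd[10, 9], 1)
  expect_equal(sum(outd), 1)
})

test_that("warp by T then by a fit of swapped samples restores the interior", {
  set.seed(26)
  # smooth image
  g <- expand.grid(r = 1:40, c = 1:40)
  img <- matrix(0.5 + 0.4 * sin(g$r / 5) * cos(g$c / 6), 40)
  Tsm <- poly_transform(rbind(c(1.02, 0.01, 0, 1e-4, 0, 1.0),
                              c(0.01, 0.98, 1e-4, 0, 0, -0.5)))
  pts <- as.matrix(expand.grid(m = seq(2, 37, 2.5), n = seq(2, 37, 2.5)))
  fwd <- poly_apply(Tsm, pts)
  Tinv <- fit_poly_wls(fwd, pts)
  w1 <- warp_image_poly(img, Tsm)
  w2 <- warp_image_poly(w1, Tinv)
  interior <- as.matrix(expand.grid(r = 8:32, c = 8:32))
  rmse <- sqrt(mean((w2[interior] - img[interior])^2))
  expect_lt(rmse, 0.02)   # interpolation-bound tolerance on a smooth image
})

test_that("JSON round-trip preserves the transform", {
  M <- rbind(c(1.5, 0, 1e-3, 0, 0, 2), c(0, 0.9, 0, -1e-3, 0, -3))
  tr <- poly_transform(M, frame = "wf->uwf")
  js <- poly_transform_to_json(tr)
  tr2 <- poly_transform_from_json(js)
  expect_equal(tr2$M, tr$M)
  expect_identical(tr2$frame, "wf->uwf")
})
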