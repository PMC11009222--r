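# Vessel-map extraction, keypoint detection/description, matching.

test_that("ridge filter lights up a dark line and stays off elsewhere", {
  img <- matrix(0.8, 64, 64)
  img[, 31:33] <- 0.2          # vertical dark line, 3 px wide
  vm <- extract_vessel_map(img)
  line_mean <- mean(vm[10:55, 31:33])
  bg_mean <- mean(vm[10:55, c(5:20, 45:60)])
  expect_gt(line_mean, 5 * max(bg_mean, 1e-6))
  expect_warning(vm0 <- extract_vessel_map(matrix(0.5, 32, 32)), "constant")
  expect_true(all(vm0 == 0))
})

test_that("extracted vessel map recovers the phantom ground truth", {
  sc <- standard_scene()
  ev <- extract_vessel_map(sc$fields[[1]]$image)
  expect_gt(dice(ev, (sc$fields[[1]]$vm > 0.5) * 1), 0.5)
  # deterministic for fixed input
  expect_identical(ev, extract_vessel_map(sc$fields[[1]]$image))
})

test_that("keypoints land on a synthetic X-crossing, deterministically", {
  img <- matrix(0, 64, 64)
  for (i in 5:60) {                 # X crossing at (32, 32) 0-based
    img[i, i] <- 1; img[i, 65 - i] <- 1
    img[i, min(64, i + 1)] <- 1; img[i, max(1, 64 - i)] <- 1
  }
  kp <- detect_keypoints(img)
  expect_gt(nrow(kp$points), 0)
  d <- sqrt((kp$points$m - 32)^2 + (kp$points$n - 32)^2)
  expect_lt(min(d), 2)
  # responses sorted descending, rows L2-normalized
  expect_true(all(diff(kp$points$response) <= 1e-12))
  expect_equal(rowSums(kp$desc^2), rep(1, nrow(kp$desc)), tolerance = 1e-9)
  # determinism and the empty-map contract
  expect_identical(kp, detect_keypoints(img))
  expect_equal(nrow(detect_keypoints(matrix(0, 32, 32))$points), 0)
})

test_that("bidirectional matching is mutual-NN with injectivity", {
  mk <- function(v) {
    structure(list(points = data.frame(m = seq_along(v), n = 0,
                                       response = 1),
                   desc = matrix(v, ncol = 1)), class = "keypoints")
  }
  # A=[0,10], B=[1,9,100]: mutual pairs (A1,B1),(A2,B2); B3 unmatched
  m <- match_bidirectional(mk(c(0, 10)), mk(c(1, 9, 100)))
  expect_equal(length(m$w), 2)
  expect_equal(attr(m, "a_idx"), c(1L, 2L))
  expect_equal(attr(m, "b_idx"), c(1L, 2L))
  # identical sets match one-to-one
  set.seed(41)
  v <- runif(10)
  mi <- match_bidirectional(mk(v), mk(v))
  expect_equal(attr(mi, "a_idx"), attr(mi, "b_idx"))
  expect_equal(length(mi$w), 10)
  # symmetry: swapping inputs transposes the pairing (same pair set)
  a <- mk(runif(8)); b <- mk(runif(5))
  m1 <- match_bidirectional(a, b)
  m2 <- match_bidirectional(b, a)
  p1 <- paste(attr(m1, "a_idx"), attr(m1, "b_idx"))
  p2 <- paste(attr(m2, "b_idx"), attr(m2, "a_idx"))
  expect_setequal(p1, p2)
})

test_that("mutual-NN matching is injective (brute-force oracle)", {
  set.seed(42)
  for (rep in 1:20) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    A <- matrix(rnorm(na * 4), na)
    B <- matrix(rnorm(nb * 4), nb)
    a <- structure(list(points = data.frame(m = 1:na, n = 0, response = 1),
                        desc = A), class = "keypoints")
    b <- structure(list(points = data.frame(m = 1:nb, n = 0, response = 1),
                        desc = B), class = "keypoints")
    m <- match_bidirectional(a, b)
    expect_false(any(duplicated(attr(m, "a_idx"))))
    expect_false(any(duplicated(attr(m, "b_idx"))))
    # brute-force mutual-NN enumeration
    D <- as.matrix(dist(rbind(A, B)))[1:na, na + 1:nb, drop = FALSE]
    mutual <- which(outer(1:na, 1:nb, Vectorize(function(i, j) {
      which.min(D[i, ]) == j && which.min(D[, j]) == i
    })), arr.ind = TRUE)
    expect_equal(sort(attr(m, "a_idx")), sort(mutual[, 1]))
  }
})

test_that("guided re-matching respects the spatial gate", {
  set.seed(43)
  pts <- matrix(runif(40, 10, 90), ncol = 2)
  desc <- matrix(rnorm(20 * 6), 20)
  desc <- desc / sqrt(rowSums(desc^2))
  a <- structure(list(points = data.frame(m = pts[, 1], n = pts[, 2],
                                          response = 1), desc = desc),
                 class = "keypoints")
  # same points shifted by (5, 0); same descriptors
  b <- structure(list(points = data.frame(m = pts[, 1] + 5, n = pts[, 2],
                                          response = 1), desc = desc),
                 class = "keypoints")
  Tsh <- poly_transform(rbind(c(1, 0, 0, 0, 0, 5), c(0, 1, 0, 0, 0, 0)))
  m <- match_guided(a, b, Tsh, gate_px = 2)
  expect_equal(length(m$w), 20)
  expect_equal(m$dst[, 1], m$src[, 1] + 5)
  # identity transform predicts 5 px away from every target: empty
  m0 <- match_guided(a, b, poly_identity(), gate_px = 2)
  expect_equal(length(m0$w), 0)
})
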