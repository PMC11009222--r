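# Shared fixtures, built once per test run and cached.
#
# All fixtures are generated in code from fixed seeds; nothing is read
# from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard desk-scale phantom scene (512 UWF / 256 WF, 9 fields)
standard_scene <- function() {
  cached("standard_scene", function() make_scene(phantom_config(seed = 1)))
}

# a small scene for cheap smoke tests
small_scene <- function(n_fields = 2) {
  cached(paste0("small_scene_", n_fields), function() {
    make_scene(phantom_config(seed = 1, n_fields = n_fields,
                              uwf_px = 256L, wf_px = 128L))
  })
}

# synthetic match sets: k inliers under a known affine map plus
# n_out gross outliers displaced by `offset` px in seeded random directions
synthetic_matches <- function(k = 50, n_out = 0, offset = 50, seed = 42,
                              noise = 0) {
  A <- rbind(c(1.05, 0.08, 12), c(-0.06, 0.97, -5))
  pts <- retialign:::with_seed(seed, {
    src <- matrix(runif(2 * (k + n_out), 10, 240), ncol = 2)
    dst <- cbind(src, 1) %*% t(A)
    if (noise > 0) dst <- dst + matrix(rnorm(length(dst), 0, noise), ncol = 2)
    if (n_out > 0) {
      ang <- runif(n_out, 0, 2 * pi)
      out_idx <- seq_len(n_out) + k
      dst[out_idx, ] <- dst[out_idx, ] + offset * cbind(cos(ang), sin(ang))
    }
    list(src = src, dst = dst)
  })
  list(m = match_set(pts$src, pts$dst),
       inlier = c(rep(TRUE, k), rep(FALSE, n_out)),
       A = A)
}

# pose-vector helper for error reporting
pose_err <- function(pose, true_pose) {
  p <- retialign:::pose_vector(pose)
  t <- retialign:::pose_vector(true_pose)
  list(rot = max(abs(p[4:5] - t[4:5])), pos = sqrt(sum((p[1:3] - t[1:3])^2)))
}
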