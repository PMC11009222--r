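# Outlier rejection for matched keypoints.
#
# Two interchangeable rejectors:
#  * ransac_sc(): classic hypothesize-and-verify RANSAC followed by
#    consensus-set refit/re-score rounds (the locally-optimized,
#    "sample-and-consensus-sets" family). Randomized but fully
#    reproducible for a fixed seed.
#  * irls_weights(): deterministic robust reweighting — alternating
#    weighted least-squares polynomial fits with a redescending
#    (Tukey biweight) or Huber loss on the residuals. Because it contains
#    no sampling, this is the rejector the iterative 3D pose optimizer
#    requires: the pose search needs every preceding step to be
#    deterministic.

# fit src->dst with the requested model; affine is embedded as a
# poly_transform with zero quadratic columns
fit_model <- function(src, dst, w, model) {
  if (model == "poly2") return(fit_poly_wls(src, dst, w))
  if (model != "affine") stop("unknown model: ", model)
  w <- rep_len(as.numeric(w), nrow(src))
  keep <- w > 0
  if (sum(keep) < 3L) stop("need at least 3 positively weighted pairs")
  A <- cbind(src[keep, , drop = FALSE], 1) * sqrt(w[keep])
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("rank-deficient design: collinear source points")
  cf <- t(qr.coef(qrA, dst[keep, , drop = FALSE] * sqrt(w[keep])))  # 2 x 3
  M <- cbind(cf[, 1:2, drop = FALSE], matrix(0, 2, 3), cf[, 3])
  poly_transform(M)
}

model_dof <- function(model) switch(model, affine = 3L, poly2 = 6L,
                                    stop("unknown model: ", model))

match_residuals <- function(transform, m) {
  pred <- poly_apply(transform, m$src)
  sqrt(rowSums((pred - m$dst)^2))
}

#' Default RANSAC-SC configuration
#'
#' @param model `"affine"` or `"poly2"`.
#' @param n_iterations number of random minimal-sample hypotheses.
#' @param inlier_threshold_px residual threshold in pixels.
#' @param min_sample minimal sample size (defaults to the model's degrees
#'   of freedom: 3 affine, 6 poly2).
#' @param refine_rounds consensus-set refit/re-score rounds after the best
#'   hypothesis is found.
#' @param seed RNG seed; the run is fully reproducible given the seed.
#' @export
ransac_config <- function(model = "poly2", n_iterations = 500L,
                          inlier_threshold_px = 2, min_sample = NULL,
                          refine_rounds = 3L, seed = 7L) {
  if (is.null(min_sample)) min_sample <- model_dof(model)
  stopifnot(n_iterations >= 1, inlier_threshold_px > 0,
            min_sample >= model_dof(model), refine_rounds >= 0)
  list(type = "ransac_sc", model = model, n_iterations = as.integer(n_iterations),
       inlier_threshold_px = inlier_threshold_px,
       min_sample = as.integer(min_sample),
       refine_rounds = as.integer(refine_rounds), seed = as.integer(seed))
}

#' RANSAC with consensus-set refinement (RANSAC-SC)
#'
#' Seeded hypothesize-and-verify: minimal samples are drawn, a model is
#' fitted, and matches within `inlier_threshold_px` of the model form the
#' consensus set; the largest consensus (ties: smaller mean residual)
#' wins. The "SC" refinement then refits on the consensus set and
#' re-scores for `refine_rounds` rounds. Degenerate samples
#' (rank-deficient designs) are skipped.
#'
#' @param m a `"match_set"`.
#' @param cfg a [ransac_config()] list.
#' @return list with `matches` (the match set with 0/1 inlier weights)
#'   and `transform` (the `poly_transform` refitted on the final
#'   consensus set).
#' @export
ransac_sc <- function(m, cfg = ransac_config()) {
  stopifnot(inherits(m, "match_set"))
  k <- length(m$w)
  if (k < cfg$min_sample) {
    stop(sprintf("need at least %d matches, got %d", cfg$min_sample, k))
  }
  thr <- cfg$inlier_threshold_px
  best <- list(count = -1L, mean_resid = Inf, inl = NULL)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iterations)) {
      idx <- sample.int(k, cfg$min_sample)
      fit <- tryCatch(
        fit_model(m$src[idx, , drop = FALSE], m$dst[idx, , drop = FALSE],
                  1, cfg$model),
        error = function(e) NULL)
      if (is.null(fit)) next
      r <- match_residuals(fit, m)
      inl <- r < thr
      cnt <- sum(inl)
      if (cnt < cfg$min_sample) next
      mr <- mean(r[inl])
      if (cnt > best$count || (cnt == best$count && mr < best$mean_resid)) {
        best <- list(count = cnt, mean_resid = mr, inl = inl)
      }
    }
  })
  if (best$count < cfg$min_sample) {
    stop("no consensus: no hypothesis reached the minimal inlier count")
  }
  inl <- best$inl
  transform <- NULL
  for (round in seq_len(cfg$refine_rounds + 1L)) {
    transform <- fit_model(m$src, m$dst, as.numeric(inl), cfg$model)
    new_inl <- match_residuals(transform, m) < thr
    if (sum(new_inl) < cfg$min_sample) break  # keep previous consensus
    if (identical(new_inl, inl)) { inl <- new_inl; break }
    inl <- new_inl
  }
  list(matches = match_set(m$src, m$dst, as.numeric(inl)),
       transform = transform)
}

#' Default IRLS robust-reweighting configuration
#'
#' @param loss `"tukey"` (redescending biweight; gross outliers get
#'   exactly zero weight) or `"huber"`.
#' @param scale_px residual scale in pixels — set it to the expected
#'   inlier localization noise (default 1, the sub-pixel jitter of
#'   corner detection). The loss tuning constant is `4.685 * scale_px`
#'   (Tukey) or `1.345 * scale_px` (Huber), the standard 95\%-efficiency
#'   constants applied to the pixel scale.
#' @param max_iters maximum reweighting iterations.
#' @param tol convergence tolerance on the maximum weight change.
#' @param model `"poly2"` (default) or `"affine"` — the transform fitted
#'   between reweighting rounds.
#' @param lmeds_init start from a deterministic least-median-of-squares
#'   similarity consensus (exhaustive pair enumeration) instead of unit
#'   weights, which keeps the redescending loss out of contaminated
#'   local minima at high outlier fractions (default TRUE).
#' @export
irls_config <- function(loss = "tukey", scale_px = 1, max_iters = 50L,
                        tol = 1e-6, model = "poly2", lmeds_init = TRUE) {
  stopifnot(loss %in% c("tukey", "huber"), scale_px > 0, max_iters >= 1)
  list(type = "irls", loss = loss, scale_px = scale_px,
       max_iters = as.integer(max_iters), tol = tol,
       model = match.arg(model, c("poly2", "affine")),
       lmeds_init = isTRUE(lmeds_init))
}

irls_weight_fn <- function(r, loss, c0) {
  if (loss == "tukey") {
    ifelse(r < c0, (1 - (r / c0)^2)^2, 0)
  } else {
    pmin(1, c0 / pmax(r, 1e-12))
  }
}

# Deterministic least-median-of-squares initialization: every
# sufficiently separated match pair defines a 2-point similarity
# transform; the pair whose transform minimizes the median residual over
# all matches wins, and matches within max(3 * best_median, 6) px of it
# form the starting inlier set. Exhaustive pair enumeration — no
# sampling, so the result is reproducible by construction. O(k^3) in the
# match count; pairs are thinned deterministically above `cap` matches.
lmeds_similarity_init <- function(m, min_sep = 20, cap = 150L) {
  k <- nrow(m$src)
  idx <- if (k > cap) unique(round(seq(1, k, length.out = cap))) else 1:k
  best <- list(med = Inf, r = NULL)
  for (ii in seq_along(idx)[-length(idx)]) {
    for (jj in (ii + 1):length(idx)) {
      i <- idx[ii]; j <- idx[jj]
      u <- m$src[j, ] - m$src[i, ]
      den <- sum(u^2)
      if (den < min_sep^2) next
      v <- m$dst[j, ] - m$dst[i, ]
      cs <- sum(u * v) / den
      sn <- (u[1] * v[2] - u[2] * v[1]) / den
      pred <- sweep(m$src, 2, m$src[i, ])
      pred <- cbind(cs * pred[, 1] - sn * pred[, 2],
                    sn * pred[, 1] + cs * pred[, 2])
      pred <- sweep(pred, 2, m$dst[i, ], "+")
      r <- sqrt(rowSums((pred - m$dst)^2))
      md <- stats::median(r)
      if (md < best$med) best <- list(med = md, r = r)
    }
  }
  if (is.null(best$r)) return(rep(TRUE, k))
  best$r < max(3 * best$med, 6)
}

irls_rho <- function(r, loss, c0) {
  if (loss == "tukey") {
    ifelse(r < c0, c0^2 / 6 * (1 - (1 - (r / c0)^2)^3), c0^2 / 6)
  } else {
    ifelse(r <= c0, r^2 / 2, c0 * (r - c0 / 2))
  }
}

#' Deterministic IRLS inlier weighting
#'
#' Alternates a weighted least-squares second-order polynomial fit with
#' robust-loss reweighting of the residuals until the weights change by
#' less than `tol` or `max_iters` is reached. Contains no randomness: two
#' calls on identical input give bit-identical results, which is what
#' makes this rejector admissible inside the pose-optimization loop. The
#' IRLS majorization guarantees the robust objective
#' \eqn{\sum_i \rho(r_i)} is non-increasing across iterations; the per-
#' iteration objective is returned for inspection.
#'
#' @param m a `"match_set"` (at least 6 pairs); incoming weights are used
#'   as the starting point.
#' @param cfg an [irls_config()] list.
#' @return list with `matches` (weights in `[0, 1]`), `transform` (final
#'   weighted polynomial fit) and `objective` (robust objective per
#'   iteration).
#' @export
irls_weights <- function(m, cfg = irls_config()) {
  stopifnot(inherits(m, "match_set"))
  if (length(m$w) < 6L) stop("need at least 6 matches for IRLS")
  c0 <- cfg$scale_px * if (cfg$loss == "tukey") 4.685 else 1.345
  w <- rep_len(ifelse(m$w > 0, m$w, 0), length(m$w))
  if (all(w == 0)) w <- rep(1, length(w))
  model <- if (is.null(cfg$model)) "poly2" else cfg$model
  transform <- NULL
  objective <- numeric(0)
  if (!isFALSE(cfg$lmeds_init) && length(w) >= 8L) {
    sel <- lmeds_similarity_init(m)
    if (sum(sel) >= 6L) w <- as.numeric(sel)
  }
  # a redescending loss can zero out everything after a poor initial
  # fit; warm-start it with a few monotone (Huber) rounds
  if (cfg$loss == "tukey") {
    c_h <- cfg$scale_px * 1.345
    for (it in 1:5) {
      transform <- fit_model(m$src, m$dst, w, model)
      w <- irls_weight_fn(match_residuals(transform, m), "huber", c_h)
    }
  }
  for (it in seq_len(cfg$max_iters)) {
    transform <- fit_model(m$src, m$dst, w, model)
    r <- match_residuals(transform, m)
    objective <- c(objective, sum(irls_rho(r, cfg$loss, c0)))
    w_new <- irls_weight_fn(r, cfg$loss, c0)
    if (sum(w_new > 0) < 6L) {
      stop("IRLS collapsed: fewer than 6 matches retain positive weight")
    }
    if (max(abs(w_new - w)) < cfg$tol) { w <- w_new; break }
    w <- w_new
  }
  list(matches = match_set(m$src, m$dst, clamp(w, 0, 1)),
       transform = transform, objective = objective)
}

#' Run the configured rejector on a match set
#'
#' Dispatches on `cfg$type` (`"ransac_sc"` or `"irls"`).
#' @param m a `"match_set"`.
#' @param cfg [ransac_config()] or [irls_config()].
#' @return list with `matches` and `transform`.
#' @export
reject_outliers <- function(m, cfg) {
  switch(cfg$type,
         ransac_sc = ransac_sc(m, cfg),
         irls = irls_weights(m, cfg),
         stop("unknown rejector type: ", cfg$type))
}
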