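#' Feature-based affine registration of video frames
#'
#' Camera motion between a reference and a moving frame is estimated as an
#' affine transform from matched salient features: Harris corners with
#' subpixel refinement, normalised local patch descriptors, nearest-neighbour
#' matching with a ratio test, and a random-sample-consensus affine fit
#' refined by least squares on the inlier set.
#'
#' The returned transform `M` is the pull map that resamples the moving frame
#' into the reference frame: `warp_affine(moving, M)` aligns with
#' `reference`. Its translation component is the displacement of the image
#' content, so a moving frame whose content is shifted by `(dx, dy)` yields
#' `affine_translation(M) == c(dx, dy)` (up to subpixel error).
#'
#' If estimation fails (blank frame apart, too few matches, or no consensus),
#' the declared `fallback` transform is returned with attribute
#' `"failed" = TRUE`; [stabilize_sequence()] passes the previous frame's
#' transform as the fallback, exploiting temporal continuity of camera motion.
#'
#' @param reference,moving Grayscale frames (numeric matrices, same size).
#' @param fallback Transform returned when estimation fails.
#' @param max_features Maximum number of corners kept per frame.
#' @param ransac_iter RANSAC iterations.
#' @param inlier_tol Inlier residual tolerance in pixels.
#' @return An [affine_transform()] with attributes `n_inliers` and `failed`.
#' @export
estimate_affine <- function(reference, moving, fallback = affine_identity(),
                            max_features = 300, ransac_iter = 300,
                            inlier_tol = 2) {
  if (!all(dim(reference) == dim(moving)))
    abort("frames must have identical dimensions")
  if (stats::sd(reference) == 0)
    abort("reference frame is constant; registration is degenerate")
  ref_feat <- detect_features(reference, max_features)
  .estimate_affine_impl(ref_feat, moving, fallback, max_features,
                        ransac_iter, inlier_tol)
}

.estimate_affine_impl <- function(ref_feat, moving, fallback, max_features,
                                  ransac_iter, inlier_tol) {
  failed <- function() structure(fallback, failed = TRUE, n_inliers = 0L)
  if (stats::sd(moving) == 0) return(failed())
  mov_feat <- detect_features(moving, max_features)
  if (nrow(ref_feat$pts) < 6 || nrow(mov_feat$pts) < 6) return(failed())
  m <- match_features(ref_feat, mov_feat)
  if (nrow(m) < 6) return(failed())
  p <- ref_feat$pts[m[, 1], , drop = FALSE]   # reference coordinates
  q <- mov_feat$pts[m[, 2], , drop = FALSE]   # moving coordinates
  fit <- ransac_affine(p, q, ransac_iter, inlier_tol)
  if (is.null(fit)) return(failed())
  structure(fit$M, failed = FALSE, n_inliers = fit$n_inliers)
}

# ---- Harris corner detection with subpixel refinement ----------------------

detect_features <- function(img, max_features = 300, sigma = 1.2,
                            patch = 5L, border = 12L) {
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
  gy <- (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
  Sxx <- gaussian_blur(gx * gx, sigma, radius_mult = 2.5)
  Syy <- gaussian_blur(gy * gy, sigma, radius_mult = 2.5)
  Sxy <- gaussian_blur(gx * gy, sigma, radius_mult = 2.5)
  R <- (Sxx * Syy - Sxy^2) - 0.05 * (Sxx + Syy)^2
  # threshold on the interior response only: frame borders (and warp fill
  # edges) carry artificial step responses that would swamp real corners
  interior <- R[(border + 1):(h - border), (border + 1):(w - border)]
  thr <- 0.005 * max(interior)
  cand <- which(R > thr)
  ys <- ((cand - 1L) %% h) + 1L
  xs <- ((cand - 1L) %/% h) + 1L
  keep <- ys > border & ys <= h - border & xs > border & xs <= w - border
  cand <- cand[keep]; ys <- ys[keep]; xs <- xs[keep]
  if (length(cand) > 0) {
    # 3x3 non-maximum suppression, evaluated only at candidate pixels
    is_max <- rep(TRUE, length(cand))
    for (off in c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L))
      is_max <- is_max & R[cand] >= R[cand + off]
    cand <- cand[is_max]; ys <- ys[is_max]; xs <- xs[is_max]
  }
  if (length(cand) == 0)
    return(list(pts = matrix(0, 0, 2), desc = matrix(0, 0, 0)))
  ord <- order(R[cand], decreasing = TRUE)
  ord <- ord[seq_len(min(max_features, length(ord)))]
  ys <- ys[ord]; xs <- xs[ord]
  # subpixel: quadratic fit of the response surface at each corner
  ii <- cbind(ys, xs)
  gxr <- (R[cbind(ys, xs + 1L)] - R[cbind(ys, xs - 1L)]) / 2
  gyr <- (R[cbind(ys + 1L, xs)] - R[cbind(ys - 1L, xs)]) / 2
  hxx <- R[cbind(ys, xs + 1L)] - 2 * R[ii] + R[cbind(ys, xs - 1L)]
  hyy <- R[cbind(ys + 1L, xs)] - 2 * R[ii] + R[cbind(ys - 1L, xs)]
  hxy <- (R[cbind(ys + 1L, xs + 1L)] - R[cbind(ys + 1L, xs - 1L)] -
            R[cbind(ys - 1L, xs + 1L)] + R[cbind(ys - 1L, xs - 1L)]) / 4
  det <- hxx * hyy - hxy^2
  ok <- is.finite(det) & abs(det) > 1e-12
  ox <- ifelse(ok, -(hyy * gxr - hxy * gyr) / det, 0)
  oy <- ifelse(ok, -(hxx * gyr - hxy * gxr) / det, 0)
  ox <- pmin(pmax(ox, -0.5), 0.5); oy <- pmin(pmax(oy, -0.5), 0.5)
  pts <- cbind(x = xs + ox, y = ys + oy)
  # descriptors: normalised (2*patch+1)^2 patch at the integer corner
  off <- as.matrix(expand.grid(dy = -patch:patch, dx = -patch:patch))
  idx <- outer(ys + xs0_to_lin(xs, h), off[, "dy"] + off[, "dx"] * h, `+`)
  desc <- matrix(img[idx], nrow = length(ys))
  mu <- rowMeans(desc)
  sdv <- sqrt(pmax(rowMeans(desc^2) - mu^2, 1e-12))
  desc <- (desc - mu) / sdv
  list(pts = pts, desc = desc)
}

xs0_to_lin <- function(xs, h) (xs - 1L) * h - 0L  # linear index helper (adds to y)

match_features <- function(a, b, ratio = 0.9) {
  da <- a$desc; db <- b$desc
  if (nrow(da) == 0 || nrow(db) == 0) return(matrix(0L, 0, 2))
  d2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  d1 <- d2[cbind(seq_len(nrow(d2)), best)]
  d2m <- d2
  d2m[cbind(seq_len(nrow(d2)), best)] <- Inf
  second <- apply(d2m, 1, min)
  keep <- d1 <= ratio^2 * second
  # mutual consistency: the chosen moving feature must prefer this reference one
  back <- max.col(-t(d2), ties.method = "first")
  keep <- keep & back[best] == seq_len(nrow(d2))
  cbind(which(keep), best[keep])
}

solve_affine_ls <- function(p, q) {
  # least-squares M with q ~ M [p; 1]
  X <- cbind(p, 1)
  fit <- tryCatch(qr.solve(X, q), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  M <- t(fit)                     # 2 x 3
  if (abs(det(M[, 1:2])) < 1e-8) return(NULL)
  as_affine(M)
}

ransac_affine <- function(p, q, iter = 300, tol = 2) {
  n <- nrow(p)
  best <- NULL; best_n <- 5L
  tp <- t(p); tq <- t(q)
  for (i in seq_len(iter)) {
    s <- sample.int(n, 3L)
    X <- cbind(p[s, , drop = FALSE], 1)
    Mt <- tryCatch(solve(X, q[s, , drop = FALSE]), error = function(e) NULL)
    if (is.null(Mt) || abs(Mt[1, 1] * Mt[2, 2] - Mt[2, 1] * Mt[1, 2]) < 1e-8) next
    M <- t(Mt)
    pr <- M[, 1:2] %*% tp + M[, 3]
    res2 <- colSums((pr - tq)^2)
    inl <- res2 < tol^2
    ni <- sum(inl)
    if (ni > best_n) {
      best <- inl; best_n <- ni
      # consensus strong enough: more sampling cannot change the refit much
      if (i >= 20 && best_n > 0.85 * n) break
    }
  }
  if (is.null(best)) return(NULL)
  M <- solve_affine_ls(p[best, , drop = FALSE], q[best, , drop = FALSE])
  if (is.null(M)) return(NULL)
  # one re-weighting pass: refit on inliers of the refined model
  pr <- t(affine_apply(M, t(p)))
  inl <- rowSums((pr - q)^2) < tol^2
  if (sum(inl) >= 6) M <- solve_affine_ls(p[inl, , drop = FALSE], q[inl, , drop = FALSE]) %||% M
  list(M = M, n_inliers = sum(inl))
}

#' Stabilise a paired white-light / NIR sequence to its first frame
#'
#' Estimates an affine transform from each later white-light frame to frame 1
#' with [estimate_affine()] and applies the identical warp to the synchronous
#' NIR frame. The registration runs on the white-light channel only (the NIR
#' channel is dark before dye inflow). Per-frame estimation failures fall back
#' to the previous frame's transform and are recorded in the log; the
#' sequence is never aborted.
#'
#' @param scene An `icgfa_scene` (see [render_scene()]) or any list with
#'   `white`, `nir` arrays and `times`.
#' @param downscale Integer factor for the registration resolution: frames
#'   are block-mean reduced by this factor before feature matching (the warp
#'   itself stays full-resolution). The default 2 roughly quarters the
#'   registration cost at a subpixel accuracy cost well inside the 1-px
#'   budget; set 1 to register at native resolution.
#' @return The scene with warped `white` and `nir`, a logical `validity`
#'   array marking pixels that stayed inside the frame during warping, and a
#'   `stabilization` log: a tibble with one row per frame (translation,
#'   rotation, inlier count, failure flag) plus the transforms as a list
#'   column.
#' @export
stabilize_sequence <- function(scene, downscale = 2L) {
  d <- dim(scene$nir)
  if (is.null(d) || d[3] < 1) abort("empty sequence")
  Tn <- d[3]
  transforms <- vector("list", Tn)
  transforms[[1]] <- affine_identity()
  validity <- array(TRUE, dim = d)
  failed <- logical(Tn)
  n_inl <- rep(NA_integer_, Tn)
  if (Tn > 1) {
    ref <- scene$white[, , 1]
    if (stats::sd(ref) == 0) abort("reference frame is constant; registration is degenerate")
    if (any(d[1:2] %% downscale != 0)) downscale <- 1L
    shrink <- if (downscale > 1) {
      # block-mean reduction; half-res pixel centres sit at 2x - 0.5 etc.
      function(f) unclass(grid_aggregate(f, cell_px = downscale))
    } else identity
    S <- affine_transform(dx = -(downscale - 1) / 2, dy = -(downscale - 1) / 2)
    S[1, 1] <- S[2, 2] <- downscale
    Si <- affine_invert(S)
    ref_feat <- detect_features(shrink(ref), 300)
    prev <- affine_identity()
    for (t in 2:Tn) {
      Ms <- .estimate_affine_impl(ref_feat, shrink(scene$white[, , t]),
                                  fallback = affine_compose(Si, affine_compose(prev, S)),
                                  max_features = 300, ransac_iter = 300,
                                  inlier_tol = 2)
      M <- affine_compose(S, affine_compose(Ms, Si))
      failed[t] <- isTRUE(attr(Ms, "failed"))
      n_inl[t] <- attr(Ms, "n_inliers")
      attr(M, "failed") <- failed[t]; attr(M, "n_inliers") <- n_inl[t]
      transforms[[t]] <- M
      prev <- M
      ww <- warp_affine(scene$white[, , t], M)
      nn <- warp_affine(scene$nir[, , t], M)
      validity[, , t] <- attr(ww, "valid")
      scene$white[, , t] <- ww
      scene$nir[, , t] <- nn
    }
  }
  scene$validity <- validity
  scene$stabilization <- tibble::tibble(
    frame = seq_len(Tn),
    dx = vapply(transforms, function(m) m[1, 3], 0),
    dy = vapply(transforms, function(m) m[2, 3], 0),
    rotation = vapply(transforms, affine_rotation, 0),
    n_inliers = n_inl,
    failed = failed,
    transform = transforms
  )
  scene$stabilized <- TRUE
  scene
}
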