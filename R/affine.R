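#' Affine transforms on image coordinates
#'
#' Transforms are 2x3 matrices `M = [A | t]` acting on pixel coordinates
#' `(x, y)` with x increasing rightwards (columns) and y downwards (rows),
#' 1-based pixel centres: `(x', y') = A %*% c(x, y) + t`. The identity
#' transform represents "no motion". Throughout the package a transform
#' attached to a moving frame is the *pull* map used to resample it into the
#' reference frame: `stabilised(p) = moving(M p)`.
#'
#' @param dx,dy Translation in pixels.
#' @param angle Rotation in degrees, anti-clockwise in image coordinates.
#' @param shear Dimensionless horizontal shear coefficient.
#' @param center Point `c(x, y)` about which rotation/shear are applied.
#' @return A 2x3 numeric matrix of class `icgfa_affine`.
#' @export
affine_transform <- function(dx = 0, dy = 0, angle = 0, shear = 0,
                             center = c(0, 0)) {
  th <- angle * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- A %*% matrix(c(1, 0, shear, 1), 2, 2)
  t <- center - A %*% center + c(dx, dy)
  structure(cbind(A, t), class = "icgfa_affine", dimnames = NULL)
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform()

as_affine <- function(M) {
  M <- unclass(M)
  stopifnot(is.numeric(M), nrow(M) == 2, ncol(M) == 3)
  if (abs(det(M[, 1:2])) < 1e-12) abort("affine linear part is singular")
  structure(M, class = "icgfa_affine")
}

#' @param M,M1,M2 2x3 affine matrices.
#' @rdname affine_transform
#' @export
affine_invert <- function(M) {
  A <- M[, 1:2, drop = FALSE]
  Ai <- solve(A)
  as_affine(cbind(Ai, -Ai %*% M[, 3]))
}

#' @rdname affine_transform
#' @export
affine_compose <- function(M1, M2) {
  # (M1 o M2)(p) = M1(M2(p))
  A <- M1[, 1:2] %*% M2[, 1:2]
  t <- M1[, 1:2] %*% M2[, 3] + M1[, 3]
  as_affine(cbind(A, t))
}

#' @rdname affine_transform
#' @export
affine_translation <- function(M) as.numeric(M[, 3])

#' @rdname affine_transform
#' @export
affine_rotation <- function(M) {
  atan2(M[2, 1], M[1, 1]) * 180 / pi
}

# Apply M to points given as a 2 x n matrix (or length-2 vector).
affine_apply <- function(M, p) {
  p <- matrix(p, nrow = 2)
  M[, 1:2] %*% p + M[, 3]
}

#' @export
print.icgfa_affine <- function(x, ...) {
  cat(sprintf("<affine> translation (%.2f, %.2f) px, rotation %.3f deg\n",
              x[1, 3], x[2, 3], affine_rotation(x)))
  invisible(x)
}

#' Resample an image through an affine transform
#'
#' Pull-warp with bilinear interpolation: `out(p) = img(M p)` at every output
#' pixel `p`. Output pixels whose source location falls outside the input
#' frame are set to `fill` and flagged invalid.
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param M 2x3 affine matrix (see [affine_transform()]).
#' @param fill Value for out-of-frame pixels.
#' @return Numeric matrix of the same size, with a logical attribute
#'   `"valid"` marking pixels sampled inside the input frame.
#' @export
warp_affine <- function(img, M, fill = 0) {
  .warp_affine_cpp(img, unclass(M), fill)
}
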