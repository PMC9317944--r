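# Head-tilt normalization. The tilt of a face in the image plane is measured
# from the two outer eye corners (P10, P19); correction is the pure rotation
# about their midpoint that brings them onto a horizontal line. Being a
# rotation it preserves every inter-landmark distance, so ratio features of an
# already-level face are unaffected by the correction.

#' Similarity transform (rotation + uniform scale + translation)
#'
#' Represented as the 2 x 3 matrix `[[a, -b, tx], [b, a, ty]]` applied to
#' homogeneous coordinates `(x, y, 1)`.
#'
#' @param a,b,tx,ty matrix entries; the upper-left 2 x 2 block must have the
#'   rotation-plus-uniform-scale form with positive determinant.
#' @return object of class `similarity_transform` (the 2 x 3 matrix with
#'   attributes).
#' @export
similarity_transform <- function(a, b = 0, tx = 0, ty = 0) {
  m <- matrix(c(a, b, -b, a, tx, ty), nrow = 2L)
  validate_similarity_transform(m)
  structure(m, class = "similarity_transform", tilt = FALSE)
}

validate_similarity_transform <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == 2L, ncol(m) == 3L)
  if (abs(m[1L, 1L] - m[2L, 2L]) > tol || abs(m[1L, 2L] + m[2L, 1L]) > tol)
    stop("not a similarity: 2x2 block must have the form [[a,-b],[b,a]]")
  if (m[1L, 1L] * m[2L, 2L] - m[1L, 2L] * m[2L, 1L] <= 0)
    stop("not a similarity: 2x2 block must have positive determinant")
  invisible(TRUE)
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- atan2(x[2L, 1L], x[1L, 1L]) * 180 / pi
  s <- sqrt(x[1L, 1L]^2 + x[2L, 1L]^2)
  cat(sprintf(
    "<similarity_transform> rotation %.4f deg, scale %.6f, t = (%.4f, %.4f)\n",
    ang, s, x[1L, 3L], x[2L, 3L]))
  invisible(x)
}

# rotation by theta (radians) about center (cx, cy), optional uniform scale
rotation_about <- function(theta, center, scale = 1) {
  a <- scale * cos(theta)
  b <- scale * sin(theta)
  tx <- center[1L] - (a * center[1L] - b * center[2L])
  ty <- center[2L] - (b * center[1L] + a * center[2L])
  structure(matrix(c(a, b, -b, a, tx, ty), nrow = 2L),
            class = "similarity_transform", tilt = FALSE)
}

#' Estimate the tilt-correcting transform from the outer eye corners
#'
#' Solves, in closed form, for the pure rotation about the eye-corner midpoint
#' that maps P10 and P19 onto the horizontal line through that midpoint. Their
#' separation and midpoint are preserved (scale = 1), so applying the result
#' changes no inter-landmark distance.
#'
#' @param lm a [landmarks51()] object.
#' @return a `similarity_transform` flagged as a tilt correction.
#' @export
estimate_tilt_transform <- function(lm) {
  stopifnot(inherits(lm, "landmarks51"))
  p10 <- pt(lm, P_OUTER_EYE_LEFT)
  p19 <- pt(lm, P_OUTER_EYE_RIGHT)
  d <- p19 - p10
  if (sqrt(sum(d^2)) < .Machine$double.eps * 100)
    stop("degenerate geometry: outer eye corners P10 and P19 coincide")
  theta <- atan2(d[2L], d[1L])
  tf <- rotation_about(-theta, (p10 + p19) / 2)
  attr(tf, "tilt") <- TRUE
  tf
}

#' Apply a similarity transform to a landmark set
#'
#' Each point is mapped by the 2 x 3 affine product
#' `(x', y') = M %*% (x, y, 1)`.
#'
#' @param t a `similarity_transform`.
#' @param lm a [landmarks51()] object.
#' @return the transformed [landmarks51()]; `tilt_corrected` is set when `t`
#'   came from [estimate_tilt_transform()].
#' @export
apply_transform <- function(t, lm) {
  stopifnot(inherits(t, "similarity_transform"), inherits(lm, "landmarks51"))
  p <- lm$points %*% t(t[, 1:2]) + rep(1, nrow(lm$points)) %o% t[, 3L]
  # the flag is granted only by a tilt-estimated transform; any other motion
  # may re-tilt the face, so it is conservatively cleared
  landmarks51(p, source_id = lm$source_id,
              tilt_corrected = isTRUE(attr(t, "tilt")))
}

#' Level a landmark set (estimate + apply in one step)
#'
#' @inheritParams estimate_tilt_transform
#' @return the tilt-corrected [landmarks51()].
#' @export
tilt_correct <- function(lm) apply_transform(estimate_tilt_transform(lm), lm)

#' Rotation-based data augmentation
#'
#' Creates two additional copies of a landmark set, rotated by `+angle_deg`
#' and `-angle_deg` about the eye-corner midpoint; together with the original
#' this triples the sample count. Because feature extraction tilt-corrects
#' first, the augmented copies yield (up to landmark noise) the same features
#' as the original — the augmentation exercises rotation invariance rather
#' than fabricating new geometry.
#'
#' @param lm a [landmarks51()] object.
#' @param angle_deg rotation magnitude in degrees, strictly positive
#'   (default 15).
#' @return list of two [landmarks51()] objects (`plus`, `minus`).
#' @export
rotate_augment <- function(lm, angle_deg = 15) {
  stopifnot(inherits(lm, "landmarks51"))
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || angle_deg <= 0)
    stop("angle_deg must be a single strictly positive magnitude")
  ctr <- (pt(lm, P_OUTER_EYE_LEFT) + pt(lm, P_OUTER_EYE_RIGHT)) / 2
  th <- angle_deg * pi / 180
  plus <- apply_transform(rotation_about(th, ctr), lm)
  minus <- apply_transform(rotation_about(-th, ctr), lm)
  plus$source_id <- paste0(lm$source_id, "+rot")
  minus$source_id <- paste0(lm$source_id, "-rot")
  plus$tilt_corrected <- FALSE
  minus$tilt_corrected <- FALSE
  list(plus = plus, minus = minus)
}
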