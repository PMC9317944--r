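# Optional image-based landmark acquisition. The package itself ships no
# computer-vision backend: face detection and shape prediction are consumed
# through a pluggable adapter so the core pipeline installs and tests on
# landmark files alone.

#' Acquisition scale settings
#'
#' Optional detection-time resize: the image is shrunk so its width is `nW`
#' (default 200 px) before face detection, and the detected rectangle is
#' re-scaled by `sf = W / nW` before landmark prediction. Applies only inside
#' an acquisition backend, never to stored landmarks.
#'
#' @param W,H input image width and height in pixels.
#' @param nW target detection width (default 200).
#' @return list with `sf`, `nW`, `nH`.
#' @export
acquisition_scale <- function(W, H, nW = 200) {
  stopifnot(W > 0, H > 0, nW > 0)
  sf <- W / nW
  list(sf = sf, nW = nW, nH = H / sf)
}

#' Acquire a 68-point landmark set from a photograph
#'
#' @param image_path path to the image.
#' @param backend a function `(image_path, scale) -> 68 x 2 matrix` wrapping
#'   a face detector plus shape predictor (e.g. dlib's HOG detector with a
#'   palsy-aware 68-point model, via any external tool). `NULL` (the default)
#'   raises an informative error: install an image backend and pass it here.
#' @param scale optional [acquisition_scale()].
#' @return a [landmarks68()] in original-image coordinates.
#' @export
acquire_landmarks <- function(image_path, backend = NULL, scale = NULL) {
  if (is.null(backend))
    stop("no landmark-acquisition backend configured. Install an external ",
         "face-landmark tool (e.g. Python dlib with a 68-point shape ",
         "predictor) and pass a function(image_path, scale) returning a ",
         "68 x 2 coordinate matrix as `backend`.")
  if (!file.exists(image_path))
    stop("image not found: ", image_path)
  pts <- backend(image_path, scale)
  if (is.null(pts))
    stop("detection failure: no face found in ", image_path)
  landmarks68(pts, source_id = basename(image_path))
}
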