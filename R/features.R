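# The 29 facial symmetry features. On a perfectly symmetric, level face the
# paired "Max" features (max(x/y, y/x)) sit at 1, the angle features f0-f2,
# f7, f14, f22 and the slope features f4-f6 at 0, and the midline angle f23
# at 90 degrees. Larger departures indicate stronger asymmetry.

FEATURE_NAMES <- paste0("f", 0:28)

FEATURE_REGION <- c(rep("Eyebrows", 7), rep("Eyes", 7), rep("Mouth", 8),
                    "Nose", rep("Combined", 6))

# feature index lists (0-based feature numbers) for the regional subsets:
# eyes = Eyebrows + Eyes + Nose + Combined {f23, f25, f26, f27};
# mouth = Mouth + Nose + Combined
REGION_INDICES <- list(
  face = 0:28,
  eyes = c(0:13, 22L, 23L, 25L, 26L, 27L),
  mouth = c(14:21, 22L, 23:28)
)

maxratio <- function(x, y, feature) {
  if (x <= 0 || y <= 0)
    stop("degenerate geometry: zero denominator in feature ", feature)
  max(x / y, y / x)
}

#' Compute the 29 facial symmetry features
#'
#' Evaluates the full feature table from a [compute_distances()] result and
#' the underlying landmarks: angle features as absolute segment inclinations,
#' slope features signed, paired "Max" features as `max(x/y, y/x)`, the
#' left/right-versus-normalizer "Max" features as `max(x/A, y/A)` (and the
#' `W`-normalized mouth variants), and the two plain ratios `C/A`, `X/A`.
#'
#' @param ds a `distance_set` from [compute_distances()].
#' @param lm the same tilt-corrected [landmarks51()] the distances came from.
#' @return named numeric vector `f0..f28` of class `feature_vector` with
#'   attributes `region` (`"face"`) and `source_id`.
#' @export
compute_features <- function(ds, lm) {
  stopifnot(inherits(ds, "distance_set"), inherits(lm, "landmarks51"))
  d <- as.list(unclass(ds))
  wp <- attr(ds, "perimeters")
  ang <- function(i, j) abs(angle_deg(pt(lm, i), pt(lm, j)))
  N <- (d$Nl + d$Nr) / 2
  O <- (d$Ol + d$Or) / 2
  if (d$A <= 0 || d$W <= 0)
    stop("degenerate geometry: zero normalizing distance A or W")

  f <- c(
    ang(0L, 9L),                         # f0  eyebrow outer ends
    ang(2L, 7L),                         # f1  eyebrow mid points
    ang(4L, 5L),                         # f2  eyebrow inner ends
    maxratio(d$L, d$M, "f3"),            # f3  avg eyebrow heights
    slope(pt(lm, 0L), pt(lm, 9L)),       # f4
    slope(pt(lm, 2L), pt(lm, 7L)),       # f5
    slope(pt(lm, 4L), pt(lm, 5L)),       # f6
    ang(10L, 19L),                       # f7  outer eye corners
    maxratio(d$Bl, d$Br, "f8"),
    maxratio(d$D, d$E, "f9"),
    maxratio(d$H, d$I, "f10"),
    maxratio(N, O, "f11"),
    maxratio(d$Nl, d$Or, "f12"),
    maxratio(d$Nr, d$Ol, "f13"),
    ang(28L, 34L),                       # f14 mouth corners
    maxratio(d$F, d$G, "f15"),
    maxratio(d$Pl, d$Ql, "f16"),
    maxratio(d$Pu, d$Qu, "f17"),
    max(d$Vl / d$A, d$Vr / d$A),         # f18
    max(d$Pl / d$W, d$Ql / d$W),         # f19
    max(d$Pu / d$W, d$Qu / d$W),         # f20
    max(wp[["Wl"]] / d$W, wp[["Wr"]] / d$W), # f21
    ang(23L, 27L),                       # f22 nostril base row
    ang(22L, 37L),                       # f23 nose tip -> lower lip midline
    maxratio(d$J, d$K, "f24"),
    max(d$T / d$A, d$U / d$A),           # f25
    max(d$R / d$A, d$S / d$A),           # f26
    d$C / d$A,                           # f27
    d$X / d$A                            # f28
  )
  names(f) <- FEATURE_NAMES
  structure(f, class = "feature_vector", region = "face",
            source_id = lm$source_id)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> region '%s', %d features\n",
              attr(x, "region"), length(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Regional feature subsets
#'
#' `region_spec()` returns the ordered feature indices of a region: the full
#' face (29 features), the eyes (19: Eyebrows, Eyes, Nose and Combined
#' f23/f25-f27) or the mouth (15: Mouth, Nose and all Combined).
#' `select_region()` projects a feature vector (or feature matrix with
#' columns `f0..f28`) onto a region, preserving order.
#'
#' @param region one of `"face"`, `"eyes"`, `"mouth"`.
#' @return `region_spec()`: list with `name` and 0-based `indices`;
#'   `select_region()`: projected vector/matrix.
#' @export
region_spec <- function(region = c("face", "eyes", "mouth")) {
  region <- match.arg(region)
  list(name = region, indices = REGION_INDICES[[region]])
}

#' @rdname region_spec
#' @param fv a `feature_vector`, or a matrix/data.frame whose columns are the
#'   29 face features.
#' @export
select_region <- function(fv, region = c("face", "eyes", "mouth")) {
  spec <- region_spec(region)
  cols <- spec$indices + 1L
  if (is.matrix(fv) || is.data.frame(fv)) {
    if (ncol(fv) != 29L)
      stop("regional projection needs the full 29-feature matrix")
    return(fv[, cols, drop = FALSE])
  }
  stopifnot(inherits(fv, "feature_vector"))
  if (length(fv) != 29L)
    stop("regional projection needs the full 29-feature vector")
  structure(unclass(fv)[cols], class = "feature_vector", region = spec$name,
            source_id = attr(fv, "source_id"))
}

#' Landmark-to-feature pipeline
#'
#' Convenience wrapper: tilt-correct (unless already flagged), compute the
#' distance set, evaluate the 29 features and optionally project a region.
#'
#' @param lm a [landmarks51()] object.
#' @param region regional subset to return (default full face).
#' @param defs distance definition table.
#' @return a `feature_vector`.
#' @export
extract_features <- function(lm, region = "face",
                             defs = distance_definitions()) {
  stopifnot(inherits(lm, "landmarks51"))
  if (!isTRUE(lm$tilt_corrected)) lm <- tilt_correct(lm)
  fv <- compute_features(compute_distances(lm, defs), lm)
  if (region == "face") fv else select_region(fv, region)
}
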