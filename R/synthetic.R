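# Synthetic landmark data. A mirror-symmetric 51-point template stands in for
# the healthy neutral face; unilateral palsy is emulated by a regional droop
# (vertical displacement with a small outward pull, attenuated away from the
# affected region's lateral extreme), on top of which landmark-prediction
# jitter and a global similarity pose (rotation/translation/scale) are
# applied. Severity classes: SL0 healthy, SL1 slight droop, SL2 strong droop.

# canonical template coordinates at interocular (P10-P19) distance 100,
# midline x = 0, eye-corner line y = 0, y increasing downward
.template100 <- function() {
  pts <- matrix(NA_real_, 51L, 2L)
  set_p <- function(i, x, y) pts[i + 1L, ] <<- c(x, y)
  # eyebrows P0..P4 (left, outer->inner), P5..P9 (right, inner->outer)
  bx <- c(-58, -46, -34, -22, -12)
  by <- c(-22, -26, -27, -26, -22)
  for (k in 1:5) set_p(k - 1L, bx[k], by[k])
  for (k in 1:5) set_p(4L + k, -bx[6L - k], by[6L - k])
  # eyes P10..P15 (left), P16..P21 (right)
  ex <- c(-50, -42, -28, -20, -28, -42)
  ey <- c(0, -5, -5, 0, 5, 5)
  for (k in 1:6) set_p(9L + k, ex[k], ey[k])
  rx <- c(20, 28, 42, 50, 42, 28)   # inner corner, top x2, outer, bottom x2
  ry <- c(0, -5, -5, 0, 5, 5)
  for (k in 1:6) set_p(15L + k, rx[k], ry[k])
  # nose: tip P22, nostril row P23..P27, bridge P48..P50
  set_p(22L, 0, 30)
  nx <- c(-12, -6, 0, 6, 12)
  ny <- c(36, 38, 39, 38, 36)
  for (k in 1:5) set_p(22L + k, nx[k], ny[k])
  set_p(48L, 0, 2); set_p(49L, 0, 12); set_p(50L, 0, 22)
  # outer lip P28..P39 (P28 left corner, P31 top mid, P34 right, P37 bottom mid)
  ox <- c(-25, -15, -6, 0, 6, 15, 25, 15, 6, 0, -6, -15)
  oy <- c(60, 56, 54, 55, 54, 56, 60, 66, 69, 70, 69, 66)
  for (k in 1:12) set_p(27L + k, ox[k], oy[k])
  # inner lip P40..P47
  ix <- c(-20, -7, 0, 7, 20, 7, 0, -7)
  iy <- c(60, 58, 59, 58, 60, 63, 64, 63)
  for (k in 1:8) set_p(39L + k, ix[k], iy[k])
  pts
}

# P-index relabelling under reflection about the vertical midline
MIRROR_MAP <- local({
  m <- c(9:5, 4:0,                        # eyebrows
         19L, 18L, 17L, 16L, 21L, 20L,    # left eye -> right eye
         13L, 12L, 11L, 10L, 15L, 14L,    # right eye -> left eye
         22L, 27L, 26L, 25L, 24L, 23L,    # nose tip + base row
         34L, 33L, 32L, 31L, 30L, 29L, 28L, 39L, 38L, 37L, 36L, 35L, # outer lip
         44L, 43L, 42L, 41L, 40L, 47L, 46L, 45L,                     # inner lip
         48L, 49L, 50L)                   # bridge (on the midline)
  stopifnot(identical(sort(m), 0:50))
  m
})

#' Mirror-symmetric face template
#'
#' Builds an anatomically plausible, exactly mirror-symmetric 51-point layout
#' with level outer eye corners, scaled to the requested interocular distance.
#' Its feature vector is the symmetric fixed point (paired Max features = 1,
#' horizontal angles and slopes = 0, midline angle f23 = 90).
#'
#' @param interocular outer-eye-corner distance in pixels (default 100).
#' @return a `face_template`: a [landmarks51()] with attribute `midline_x`.
#' @export
make_template <- function(interocular = 100) {
  if (!is.numeric(interocular) || interocular <= 0)
    stop("interocular scale must be positive")
  lm <- landmarks51(.template100() * (interocular / 100),
                    source_id = "template", tilt_corrected = TRUE)
  attr(lm, "midline_x") <- 0
  class(lm) <- c("face_template", class(lm))
  lm
}

#' Mirror a landmark set about a vertical axis, with left/right relabelling
#'
#' Reflects x about `axis_x` and renumbers points so left-side landmarks take
#' their right homologue's index (and vice versa). A symmetric template is a
#' fixed point of this map; features are invariant under it, which is why the
#' features cannot identify the affected side.
#'
#' @param lm a [landmarks51()] object.
#' @param axis_x x-coordinate of the mirror axis (default: eye-corner
#'   midpoint).
#' @return the mirrored [landmarks51()].
#' @export
mirror_landmarks <- function(lm, axis_x = NULL) {
  stopifnot(inherits(lm, "landmarks51"))
  if (is.null(axis_x))
    axis_x <- (pt(lm, P_OUTER_EYE_LEFT)[1L] + pt(lm, P_OUTER_EYE_RIGHT)[1L]) / 2
  p <- lm$points
  p[, 1L] <- 2 * axis_x - p[, 1L]
  landmarks51(p[MIRROR_MAP + 1L, , drop = FALSE],
              source_id = paste0(lm$source_id, "|mirror"),
              tilt_corrected = lm$tilt_corrected)
}

# Affected points and per-point droop attenuation by facial region (left
# side; the right-side profile is the mirror relabelling, so midline points
# such as the lip midlines P31/P37 receive the same weight from either side).
# Brow: sag strongest at the lateral end. Eye: lower-lid sag (bottom points
# dominate, inner canthus anchored). Mouth: corner droops most, with the lip
# midline deviating at half weight. Weights are chosen so every affected
# feature moves monotonically as the droop magnitude grows.
.droop_profile_left <- list(
  brow = list(idx = 0:4, w = c(1, 0.8, 0.6, 0.4, 0.2)),
  eye = list(idx = 10:15, w = c(0.4, 0.2, 0.2, 0, 1, 1)),
  mouth = list(idx = c(28L, 29L, 30L, 31L, 37L, 38L, 39L, 40L, 41L, 47L),
               w = c(1, 0.8, 0.65, 0.25, 0.5, 0.8, 0.9, 0.9, 0.6, 0.7))
)

#' Unilateral palsy perturbation
#'
#' `palsy_perturbation()` describes a one-sided droop: per-region magnitudes
#' in pixels (at the template's scale) for the brow, eye and mouth.
#' `apply_palsy()` displaces the affected side's points downward by the
#' region magnitude times a fixed per-point attenuation (strongest at the
#' region's most mobile point), with a small outward lateral pull (0.1 x
#' magnitude) on the mouth points; the contralateral side is untouched.
#' Deterministic: landmark jitter is added separately by
#' [generate_dataset()].
#'
#' @param side `"left"` or `"right"`.
#' @param brow,eye,mouth droop magnitudes in pixels, `>= 0`.
#' @param severity_class label carried along (`"SL1"` or `"SL2"`).
#' @return `palsy_perturbation()`: a perturbation description;
#'   `apply_palsy()`: the perturbed
#'   [landmarks51()].
#' @export
palsy_perturbation <- function(side = c("left", "right"), brow = 0, eye = 0,
                               mouth = 0, severity_class = "SL1") {
  side <- match.arg(side)
  if (min(brow, eye, mouth) < 0)
    stop("droop magnitudes must be >= 0")
  structure(list(side = side, brow = brow, eye = eye, mouth = mouth,
                 severity_class = severity_class),
            class = "palsy_perturbation")
}

#' @rdname palsy_perturbation
#' @param template a `face_template` (or any [landmarks51()]).
#' @param p a `palsy_perturbation`.
#' @export
apply_palsy <- function(template, p) {
  stopifnot(inherits(template, "landmarks51"),
            inherits(p, "palsy_perturbation"))
  pts <- template$points
  scl <- euclid(pt(template, P_OUTER_EYE_LEFT),
                pt(template, P_OUTER_EYE_RIGHT)) / 100
  outward <- if (p$side == "left") -1 else 1
  for (reg in names(.droop_profile_left)) {
    prof <- .droop_profile_left[[reg]]
    idx <- if (p$side == "left") prof$idx else MIRROR_MAP[prof$idx + 1L]
    mag <- p[[reg]] * scl
    pts[idx + 1L, 2L] <- pts[idx + 1L, 2L] + mag * prof$w
    if (reg == "mouth")
      pts[idx + 1L, 1L] <- pts[idx + 1L, 1L] + outward * 0.1 * mag * prof$w
  }
  landmarks51(pts, source_id = paste0(template$source_id, "|", p$side, "|",
                                      p$severity_class),
              tilt_corrected = FALSE)
}

#' Synthetic dataset configuration
#'
#' Defaults state the generator's world: interocular 100 px; landmark jitter
#' sd 0.5 px; global pose uniform in rotation +/-15 degrees, translation
#' +/-20 px, scale 0.8-1.2; severity profiles SL1 droop U(3, 6) px and SL2
#' droop U(8, 16) px per region at interocular 100.
#'
#' @param n_per_class samples per severity class (>= 1).
#' @param interocular template scale in pixels.
#' @param jitter_sd Gaussian landmark noise sd in pixels (>= 0).
#' @param rot_deg,trans_px half-ranges of the uniform pose rotation and
#'   translation.
#' @param scale_range length-2 uniform range of the pose scale factor.
#' @param sl1_range,sl2_range length-2 uniform ranges of the per-region droop
#'   magnitude (pixels at interocular 100) for the two palsy classes.
#' @param class_mix optional named integer vector overriding `n_per_class`
#'   per class, e.g. `c(SL0 = 740, SL1 = 208, SL2 = 472)` to emulate the
#'   healthy-heavy mixtures of the clinical assemblies.
#' @param seed integer fixing the full generator stream.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_class = 20L, interocular = 100,
                         jitter_sd = 0.5, rot_deg = 15, trans_px = 20,
                         scale_range = c(0.8, 1.2), sl1_range = c(3, 6),
                         sl2_range = c(8, 16), class_mix = NULL, seed = 1L) {
  stopifnot(n_per_class >= 1L, jitter_sd >= 0, interocular > 0,
            length(scale_range) == 2L, all(scale_range > 0),
            length(sl1_range) == 2L, length(sl2_range) == 2L)
  structure(list(n_per_class = as.integer(n_per_class),
                 interocular = interocular, jitter_sd = jitter_sd,
                 rot_deg = rot_deg, trans_px = trans_px,
                 scale_range = scale_range, sl1_range = sl1_range,
                 sl2_range = sl2_range, class_mix = class_mix,
                 seed = as.integer(seed)),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a labeled synthetic landmark dataset
#'
#' Draws, per sample: a severity class (SL0/SL1/SL2), an affected side and
#' per-region droop magnitudes (palsy classes only), Gaussian landmark
#' jitter, and a global similarity pose. Features are extracted through the
#' regular pipeline (tilt correction first), so the pose exercises the
#' correction path. The stream is a pure function of the config.
#'
#' @param cfg a [synth_config()].
#' @return a `labeled_dataset` (see [labeled_dataset()]) with the landmark
#'   sets attached as attribute `landmarks`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  counts <- cfg$class_mix
  if (is.null(counts))
    counts <- c(SL0 = cfg$n_per_class, SL1 = cfg$n_per_class,
                SL2 = cfg$n_per_class)
  stopifnot(all(names(counts) %in% c("SL0", "SL1", "SL2")))
  template <- make_template(cfg$interocular)
  scl <- cfg$interocular / 100

  with_seed(cfg$seed, {
    lms <- list(); labels <- character(0); subjects <- character(0)
    for (cls in names(counts)) {
      for (i in seq_len(counts[[cls]])) {
        lm <- template
        if (cls != "SL0") {
          rng <- if (cls == "SL1") cfg$sl1_range else cfg$sl2_range
          pert <- palsy_perturbation(
            side = sample(c("left", "right"), 1L),
            brow = stats::runif(1, rng[1L], rng[2L]),
            eye = stats::runif(1, rng[1L], rng[2L]),
            mouth = stats::runif(1, rng[1L], rng[2L]),
            severity_class = cls)
          lm <- apply_palsy(template, pert)
        }
        pts <- lm$points +
          matrix(stats::rnorm(102L, sd = cfg$jitter_sd * scl), 51L, 2L)
        lm <- landmarks51(pts, source_id = sprintf("synth_%s_%04d", cls, i))
        ctr <- (pt(lm, P_OUTER_EYE_LEFT) + pt(lm, P_OUTER_EYE_RIGHT)) / 2
        pose <- rotation_about(stats::runif(1, -cfg$rot_deg, cfg$rot_deg) *
                                 pi / 180, ctr,
                               scale = stats::runif(1, cfg$scale_range[1L],
                                                    cfg$scale_range[2L]))
        pose[, 3L] <- pose[, 3L] +
          stats::runif(2, -cfg$trans_px, cfg$trans_px) * scl
        lm <- apply_transform(pose, lm)
        lm$source_id <- sprintf("synth_%s_%04d", cls, i)
        lms[[length(lms) + 1L]] <- lm
        labels <- c(labels, cls)
        subjects <- c(subjects, lm$source_id)
      }
    }
    feats <- t(vapply(lms, function(l) as.numeric(extract_features(l)),
                      numeric(29L)))
    colnames(feats) <- FEATURE_NAMES
    ds <- labeled_dataset(feats, labels, subject_id = subjects,
                          region = "face")
    attr(ds, "landmarks") <- lms
    ds
  })
}
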