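# Geometric primitives and the 28 named inter-landmark distances plus the two
# eyebrow-height averages on which the 29 symmetry features are built.

#' Geometric primitives
#'
#' `angle_deg()` returns the inclination of the segment `PaPb` relative to
#' horizontal, in degrees folded into `(-90, 90]` so the value does not depend
#' on endpoint order (horizontal segment -> 0, vertical -> 90). `slope()` is
#' the plain difference quotient dy/dx. `euclid()` is the Euclidean distance.
#' `perimeter()` is the closed-shape perimeter: consecutive edge lengths plus
#' the closing edge from the last point back to the first.
#'
#' @param pa,pb numeric length-2 points `(x, y)`.
#' @return a scalar (degrees, dimensionless slope, or pixels).
#' @export
angle_deg <- function(pa, pb) {
  d <- pa - pb
  if (all(abs(d) < .Machine$double.eps * 100))
    stop("degenerate geometry: angle of coincident points")
  ang <- atan2(d[2L], d[1L]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' @rdname angle_deg
#' @export
slope <- function(pa, pb) {
  dx <- pa[1L] - pb[1L]
  if (abs(dx) < .Machine$double.eps * 100)
    stop("degenerate geometry: slope of a vertical segment is undefined")
  (pa[2L] - pb[2L]) / dx
}

#' @rdname angle_deg
#' @export
euclid <- function(pa, pb) sqrt(sum((pa - pb)^2))

#' @rdname angle_deg
#' @param shape numeric `n x 2` matrix of vertices in order, `n >= 3`.
#' @export
perimeter <- function(shape) {
  shape <- as.matrix(shape)
  if (nrow(shape) < 3L)
    stop("a closed shape requires at least 3 points")
  closed <- rbind(shape, shape[1L, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Distance definition table
#'
#' The endpoints of the 28 named distances (and the point lists for the
#' eyebrow-height averages L/M and the outer-lip half-perimeters Wl/Wr) are a
#' figure-derived convention, so they ship as an editable CSV with columns
#' `name`, `kind` (`dist`, `brow_height`, `perimeter`) and `points`
#' (space-separated 0-based P indices). Every left/right pair is homologous
#' under mirror relabelling; `A` (outer-eye-corner distance) is the global
#' normalizer.
#'
#' @param path optional path to an alternative definition CSV.
#' @return data frame with a parsed `idx` list-column (validated).
#' @export
distance_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "distance_definitions.csv",
                        package = "facesym", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("A", "Bl", "Br", "C", "D", "E", "F", "G", "H", "I", "J", "K",
            "Nl", "Nr", "Ol", "Or", "Pl", "Pu", "Ql", "Qu", "R", "S", "T",
            "U", "Vl", "Vr", "W", "X", "L", "M", "Wl", "Wr")
  missing <- setdiff(need, tab$name)
  if (length(missing))
    stop("distance definition file lacks entries for: ",
         paste(missing, collapse = ", "))
  tab$idx <- lapply(strsplit(tab$points, "[ ;]+"), as.integer)
  bad <- vapply(tab$idx, function(i) anyNA(i) || any(i < 0L | i > 50L),
                logical(1L))
  if (any(bad))
    stop("invalid point indices for: ", paste(tab$name[bad], collapse = ", "))
  tab
}

DIST_NAMES <- c("A", "Bl", "Br", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                "Nl", "Nr", "Ol", "Or", "Pl", "Pu", "Ql", "Qu", "R", "S",
                "T", "U", "Vl", "Vr", "W", "X")
AVG_NAMES <- c("L", "M")
PERIM_NAMES <- c("Wl", "Wr")

#' Compute the named distance set of a landmark set
#'
#' Evaluates the 28 named distances, the two average eyebrow heights (mean
#' vertical offset of each brow's points from the outer-eye-corner line) and
#' the two outer-lip half-perimeters, per the shipped definition table.
#'
#' @param lm a tilt-corrected [landmarks51()] object.
#' @param defs definition table from [distance_definitions()].
#' @param require_tilt error if `lm` is not flagged tilt-corrected
#'   (default TRUE: angle and height measures presume a level face).
#' @return named numeric vector of class `distance_set` (30 values: 28
#'   distances + L + M) with attribute `perimeters` holding Wl and Wr.
#' @export
compute_distances <- function(lm, defs = distance_definitions(),
                              require_tilt = TRUE) {
  stopifnot(inherits(lm, "landmarks51"))
  if (require_tilt && !isTRUE(lm$tilt_corrected))
    stop("landmarks must be tilt-corrected first (see tilt_correct); ",
         "pass require_tilt = FALSE to override")
  p <- lm$points
  row <- function(nm) defs$idx[[match(nm, defs$name)]]
  ref_y <- mean(p[c(P_OUTER_EYE_LEFT, P_OUTER_EYE_RIGHT) + 1L, 2L])

  val <- vapply(DIST_NAMES, function(nm) {
    i <- row(nm)
    if (length(i) != 2L)
      stop("distance '", nm, "' must be defined by exactly two points")
    euclid(p[i[1L] + 1L, ], p[i[2L] + 1L, ])
  }, numeric(1L))
  avg <- vapply(AVG_NAMES, function(nm) {
    mean(abs(ref_y - p[row(nm) + 1L, 2L]))
  }, numeric(1L))
  per <- vapply(PERIM_NAMES, function(nm) {
    perimeter(p[row(nm) + 1L, , drop = FALSE])
  }, numeric(1L))

  if (val[["A"]] <= 0 || val[["W"]] <= 0)
    stop("degenerate geometry: normalizing distances A and W must be positive")
  structure(c(val, avg), class = "distance_set", perimeters = per,
            source_id = lm$source_id)
}

#' @export
print.distance_set <- function(x, ...) {
  cat("<distance_set> 28 distances + 2 averages (px):\n")
  print(round(unclass(x), 3))
  cat("outer-lip half-perimeters:\n")
  print(round(attr(x, "perimeters"), 3))
  invisible(x)
}
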