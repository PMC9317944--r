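# Landmark index conventions (0-based, as in the dlib/iBUG 68-point layout and
# the renumbered P0..P50 scheme):
#   P0..P9   eyebrows (left outer -> left inner, right inner -> right outer)
#   P10..P21 eyes (left eye counter-clockwise from outer corner, then right)
#   P22      nose tip, P23..P27 nostril base row
#   P28..P39 outer lip (P28 left corner, P34 right corner)
#   P40..P47 inner lip
#   P48..P50 nose bridge
# P10 and P19 are the outer eye corners used for tilt correction.

P_OUTER_EYE_LEFT <- 10L
P_OUTER_EYE_RIGHT <- 19L

.lm_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("landmark points must be an n x 2 matrix of (x, y) coordinates")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  points
}

#' Landmark set containers
#'
#' A `landmarks68` holds the 68 points of the standard full-face model; a
#' `landmarks51` holds the 51 renumbered points `P0..P50` actually used for
#' symmetry analysis. Both are thin wrappers around an `n x 2` coordinate
#' matrix (image convention: x to the right, y downward, units of pixels).
#'
#' @param points numeric `n x 2` matrix (or coercible) of (x, y) coordinates.
#' @param source_id free-text sample identifier.
#' @param tilt_corrected has the set been levelled by [estimate_tilt_transform()]?
#' @return an object of class `landmarks68` or `landmarks51`.
#' @seealso [renumber_landmarks()], [read_landmarks()]
#' @export
landmarks68 <- function(points, source_id = "") {
  points <- .lm_points(points)
  if (nrow(points) != 68L)
    stop("a landmarks68 set requires exactly 68 points, got ", nrow(points))
  structure(list(points = points, source_id = as.character(source_id)),
            class = c("landmarks68", "landmark_set"))
}

#' @rdname landmarks68
#' @export
landmarks51 <- function(points, source_id = "", tilt_corrected = FALSE) {
  points <- .lm_points(points)
  if (nrow(points) != 51L)
    stop("a landmarks51 set requires exactly 51 points, got ", nrow(points))
  structure(list(points = points, source_id = as.character(source_id),
                 tilt_corrected = isTRUE(tilt_corrected)),
            class = c("landmarks51", "landmark_set"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<%s> %d points, source_id='%s'%s\n", class(x)[1L],
              nrow(x$points), x$source_id,
              if (isTRUE(x$tilt_corrected)) ", tilt-corrected" else ""))
  invisible(x)
}

# points of a landmark set, 0-based P index
pt <- function(lm, i) lm$points[i + 1L, ]

#' Default 68-to-51 renumbering table
#'
#' Reads the mapping from the packaged CSV (columns `idx68`, `idxP`, both
#' 0-based) and validates it: a bijection from 51 of the 68 model indices onto
#' `0..50`, dropping the 17 face-contour points, with the outer eye corners at
#' P10/P19 and the mouth corners at P28/P34.
#'
#' @param path optional path to an alternative mapping CSV.
#' @return integer vector of length 51; element `i` is the 0-based 68-model
#'   index mapped to `P(i-1)`.
#' @export
default_landmark_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "landmark_map_68to51.csv",
                        package = "facesym", mustWork = TRUE)
  tab <- utils::read.csv(path)
  validate_landmark_mapping(tab)
  m <- integer(51L)
  m[tab$idxP + 1L] <- as.integer(tab$idx68)
  m
}

#' @rdname default_landmark_mapping
#' @param mapping data frame with columns `idx68`, `idxP`.
#' @export
validate_landmark_mapping <- function(mapping) {
  if (!all(c("idx68", "idxP") %in% names(mapping)))
    stop("mapping must have columns idx68 and idxP")
  if (nrow(mapping) != 51L)
    stop("mapping must have exactly 51 rows, got ", nrow(mapping))
  if (anyDuplicated(mapping$idx68) || any(mapping$idx68 < 0) ||
      any(mapping$idx68 > 67))
    stop("mapping idx68 must be 51 distinct indices in 0..67")
  if (!identical(sort(as.integer(mapping$idxP)), 0:50))
    stop("mapping idxP must be a permutation of 0..50")
  invisible(TRUE)
}

#' Renumber a 68-point landmark set to the 51-point scheme
#'
#' Drops the face-contour points and reorders the remaining 51 landmarks into
#' the `P0..P50` numbering on which all distance and feature definitions are
#' based. Coordinates are untouched.
#'
#' @param full a [landmarks68()] object.
#' @param mapping integer vector of length 51 as returned by
#'   [default_landmark_mapping()] (0-based 68-model indices in P order).
#' @return a [landmarks51()] object.
#' @export
renumber_landmarks <- function(full, mapping = default_landmark_mapping()) {
  if (!inherits(full, "landmarks68"))
    stop("renumber_landmarks expects a landmarks68 object")
  mapping <- as.integer(mapping)
  if (length(mapping) != 51L || anyDuplicated(mapping) ||
      any(mapping < 0L) || any(mapping > 67L))
    stop("mapping must be 51 distinct 0-based indices below 68")
  landmarks51(full$points[mapping + 1L, , drop = FALSE],
              source_id = full$source_id)
}

#' Read and write landmark sets
#'
#' CSV files use columns `index,x,y` (0-based index); JSON files hold a list
#' of `[x, y]` pairs. The point count (68 or 51) decides the returned class.
#'
#' @param path file to read or write.
#' @param source_id identifier attached to the returned set (default: the
#'   file name).
#' @return [landmarks68()] or [landmarks51()] for `read_landmarks()`;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path, source_id = basename(path)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    coords <- jsonlite::fromJSON(path)
    pts <- if (is.list(coords)) do.call(rbind, coords) else as.matrix(coords)
  } else {
    tab <- utils::read.csv(path)
    need <- c("index", "x", "y")
    if (!all(need %in% names(tab)))
      stop("malformed landmark CSV '", path, "': need columns index,x,y")
    if (anyNA(tab$x) || anyNA(tab$y))
      stop("malformed landmark CSV '", path, "': non-numeric coordinates")
    pts <- as.matrix(tab[order(tab$index), c("x", "y")])
  }
  switch(as.character(nrow(pts)),
         "68" = landmarks68(pts, source_id),
         "51" = landmarks51(pts, source_id),
         stop("landmark file '", path, "' has ", nrow(pts),
              " points; expected 68 or 51"))
}

#' @rdname read_landmarks
#' @param lm a landmark set.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unname(split(lm$points, row(lm$points)[, 1L])), path,
                         digits = NA)
  } else {
    utils::write.csv(data.frame(index = seq_len(nrow(lm$points)) - 1L,
                                x = lm$points[, 1L], y = lm$points[, 2L]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
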