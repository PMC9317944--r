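# Labeled feature datasets and the clinical-style experiment assembly:
# per-subject image caps, regional projection, task label collapse and
# rotation augmentation (original + two opposite rotations = 3x).

#' Labeled feature dataset
#'
#' @param features numeric `n x p` matrix (rows = samples).
#' @param labels class labels, length `n`.
#' @param subject_id per-sample subject identifiers (length `n`).
#' @param region region tag of the feature columns.
#' @param augmented_from optional parent sample id per row (`NA` for
#'   originals).
#' @return a `labeled_dataset` list.
#' @export
labeled_dataset <- function(features, labels, subject_id = NULL,
                            region = "face", augmented_from = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  labels <- factor(labels)
  if (length(labels) != n) stop("labels must match the number of rows")
  if (is.null(subject_id)) subject_id <- sprintf("s%05d", seq_len(n))
  if (length(subject_id) != n) stop("subject_id must match the number of rows")
  if (is.null(augmented_from)) augmented_from <- rep(NA_character_, n)
  structure(list(features = features, labels = labels,
                 subject_id = as.character(subject_id),
                 region = region,
                 augmented_from = as.character(augmented_from)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, region '%s'\n",
              nrow(x$features), ncol(x$features), x$region))
  print(table(x$labels))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds a `labeled_dataset`.
#' @export
n_samples <- function(ds) nrow(ds$features)

subset_dataset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE],
                  droplevels(ds$labels[idx]), ds$subject_id[idx],
                  region = ds$region, augmented_from = ds$augmented_from[idx])
}

collapse_task_labels <- function(labels, task) {
  labels <- as.character(labels)
  switch(task,
         detect = factor(ifelse(labels == "SL0", "0", "1"),
                         levels = c("0", "1")),
         two_level = {
           if (any(labels == "SL0"))
             stop("two_level task admits only SL1/SL2 samples")
           factor(labels, levels = c("SL1", "SL2"))
         },
         three_level = factor(labels, levels = c("SL0", "SL1", "SL2")),
         stop("unknown task '", task, "'"))
}

#' Assemble a classification experiment from labeled landmark sets
#'
#' Reproduces the clinical dataset-building protocol: cap the number of
#' images per subject, collapse severity labels to the task's label set
#' (`detect`: SL0 -> 0, SL1/SL2 -> 1; `two_level`: SL1 vs SL2; `three_level`:
#' SL0/SL1/SL2), optionally triple the data by rotating every landmark set in
#' two opposite directions, and project the requested feature region. All
#' features (including the augmented copies) are extracted through tilt
#' correction.
#'
#' @param landmarks list of [landmarks51()] objects.
#' @param labels per-sample severity labels (`SL0`, `SL1`, `SL2`).
#' @param subject_id per-sample subject identifiers.
#' @param task `"detect"`, `"two_level"` or `"three_level"`.
#' @param region `"face"`, `"eyes"` or `"mouth"`.
#' @param per_subject_cap maximum images kept per subject (`Inf` = no cap;
#'   the clinical protocol used 20 or 40).
#' @param augment add the two opposite rotations of every kept sample.
#' @param angle_deg augmentation rotation magnitude (degrees).
#' @param defs distance definition table.
#' @return a `labeled_dataset`; augmented rows carry their parent id in
#'   `augmented_from`.
#' @export
assemble_experiment <- function(landmarks, labels, subject_id,
                                task = c("detect", "two_level", "three_level"),
                                region = c("face", "eyes", "mouth"),
                                per_subject_cap = Inf, augment = FALSE,
                                angle_deg = 15,
                                defs = distance_definitions()) {
  task <- match.arg(task)
  region <- match.arg(region)
  stopifnot(length(landmarks) == length(labels),
            length(labels) == length(subject_id))
  keep <- unlist(lapply(split(seq_along(landmarks), subject_id), function(i)
    utils::head(i, per_subject_cap)), use.names = FALSE)
  keep <- sort(keep)
  landmarks <- landmarks[keep]
  labels <- labels[keep]
  subject_id <- as.character(subject_id)[keep]

  y <- collapse_task_labels(labels, task)
  ids <- vapply(landmarks, function(l) l$source_id, character(1L))
  parent <- rep(NA_character_, length(landmarks))
  if (augment) {
    extra <- lapply(landmarks, rotate_augment, angle_deg = angle_deg)
    landmarks <- c(landmarks, unlist(extra, recursive = FALSE))
    y <- factor(c(as.character(y), rep(as.character(y), each = 2L)),
                levels = levels(y))
    subject_id <- c(subject_id, rep(subject_id, each = 2L))
    parent <- c(parent, rep(ids, each = 2L))
  }
  if (any(table(y) == 0L))
    stop("empty class after assembly for task '", task, "'")
  feats <- t(vapply(landmarks,
                    function(l) as.numeric(extract_features(l, defs = defs)),
                    numeric(29L)))
  colnames(feats) <- FEATURE_NAMES
  feats <- select_region(feats, region)
  labeled_dataset(feats, y, subject_id, region = region,
                  augmented_from = parent)
}
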