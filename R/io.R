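# Feature-matrix CSV interchange: one row per sample, columns source_id,
# label, then the feature columns in canonical order.

#' Read and write feature-matrix CSV files
#'
#' @param ds a `labeled_dataset`.
#' @param path CSV file.
#' @return `read_feature_csv()` returns a `labeled_dataset`;
#'   `write_feature_csv()` returns `path` invisibly.
#' @export
write_feature_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- data.frame(source_id = ds$subject_id,
                   label = as.character(ds$labels),
                   ds$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param region region tag recorded on the returned dataset.
#' @export
read_feature_csv <- function(path, region = "face") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("source_id", "label") %in% names(df)))
    stop("feature CSV must have source_id and label columns")
  fcols <- setdiff(names(df), c("source_id", "label"))
  feat <- as.matrix(df[, fcols, drop = FALSE])
  if (!is.numeric(feat)) stop("non-numeric feature values in ", path)
  labeled_dataset(feat, df$label, subject_id = df$source_id, region = region)
}
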