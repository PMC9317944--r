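# Dense ARFF (Attribute-Relation File Format) interchange: numeric feature
# attributes in canonical f-order followed by one nominal class attribute.

#' Write a labeled dataset as a dense ARFF file
#'
#' @param ds a `labeled_dataset` (homogeneous feature dimensionality).
#' @param path output file.
#' @param relation relation name for the `@relation` header.
#' @return `path`, invisibly.
#' @export
write_arff <- function(ds, path, relation = "facesym") {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (n_samples(ds) == 0L) stop("cannot serialize an empty dataset")
  feat <- ds$features
  if (is.null(colnames(feat))) colnames(feat) <- paste0("f", seq_len(ncol(feat)) - 1L)
  lev <- levels(droplevels(ds$labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", relation), con)
  writeLines(sprintf("@attribute %s numeric", colnames(feat)), con)
  writeLines(sprintf("@attribute class {%s}", paste(lev, collapse = ",")), con)
  writeLines("@data", con)
  rows <- apply(feat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(paste(rows, as.character(ds$labels), sep = ","), con)
  invisible(path)
}

#' Read a dense ARFF file written by [write_arff()]
#'
#' Minimal parser for the dialect this package emits (numeric attributes plus
#' one trailing nominal class attribute).
#'
#' @param path ARFF file.
#' @return a `labeled_dataset`.
#' @export
read_arff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  lower <- tolower(lines)
  data_at <- which(lower == "@data")
  if (length(data_at) != 1L) stop("malformed ARFF: missing @data section")
  attr_lines <- lines[startsWith(lower, "@attribute")]
  if (!length(attr_lines)) stop("malformed ARFF: no attribute declarations")
  parts <- regmatches(attr_lines,
                      regexec("^@attribute\\s+(\\S+)\\s+(.+)$", attr_lines,
                              ignore.case = TRUE))
  attr_names <- vapply(parts, `[`, character(1L), 2L)
  attr_types <- vapply(parts, `[`, character(1L), 3L)
  nclass <- length(attr_types)
  if (!grepl("^\\{.*\\}$", attr_types[nclass]))
    stop("malformed ARFF: last attribute must be the nominal class")
  lev <- trimws(strsplit(gsub("[{}]", "", attr_types[nclass]), ",")[[1L]])
  if (!all(tolower(attr_types[-nclass]) %in% c("numeric", "real")))
    stop("malformed ARFF: feature attributes must be numeric")
  rows <- strsplit(lines[(data_at + 1L):length(lines)], ",")
  if (any(lengths(rows) != nclass))
    stop("malformed ARFF: data row width does not match attribute count")
  feat <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r[-nclass])))
  if (anyNA(feat)) stop("malformed ARFF: non-numeric feature value")
  colnames(feat) <- attr_names[-nclass]
  labels <- vapply(rows, function(r) trimws(r[nclass]), character(1L))
  if (!all(labels %in% lev))
    stop("malformed ARFF: class value outside the declared nominal set")
  labeled_dataset(feat, factor(labels, levels = lev))
}
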