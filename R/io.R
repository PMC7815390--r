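#' Read / write a dataset manifest
#'
#' The manifest is delimited text with header `path,label,subject`; labels
#' must come from the closed 7-expression set and every record needs a
#' nonempty subject identifier.
#'
#' @param path CSV file path.
#' @return A tibble with columns `path`, `label`, `subject`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("path", "label", "subject") %in% names(m))) {
    abort("manifest must have columns path, label, subject")
  }
  bad <- setdiff(unique(m$label), EXPRESSION_LABELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown expression label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(EXPRESSION_LABELS, collapse = ", ")))
  }
  if (any(is.na(m$subject) | !nzchar(m$subject))) {
    abort("every manifest record needs a nonempty subject identifier")
  }
  m[, c("path", "label", "subject")]
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `path`, `label`, `subject`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest[, c("path", "label", "subject")], path)
  invisible(path)
}

#' Write / read an extracted feature matrix as delimited text
#'
#' One row per image; the `label` and `subject` columns come first, followed
#' by the numeric feature columns. Values round-trip exactly (full precision).
#'
#' @param features Numeric matrix, rows aligned with `manifest`.
#' @param manifest Data frame with columns `path`, `label`, `subject`.
#' @param path Output file (`.csv`).
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a list with `manifest` and `features`.
#' @export
write_features <- function(features, manifest, path) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(manifest))
  df <- data.frame(path = manifest$path, label = manifest$label,
                   subject = manifest$subject, features,
                   check.names = FALSE)
  names(df)[-(1:3)] <- sprintf("f%05d", seq_len(ncol(features)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    path = "c", label = "c", subject = "c", .default = "d"))
  list(manifest = df[, c("path", "label", "subject")],
       features = unname(as.matrix(df[, -(1:3)])))
}
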