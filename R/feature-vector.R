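# A named feature vector with per-feature validity flags. Invalid features
# carry NA values but are never silently dropped; downstream preprocessing
# treats them as missing cells.

#' Construct a feature vector with validity flags
#'
#' @param values named numeric vector.
#' @param valid named logical vector (defaults to `is.finite(values)`).
#' @param meta optional list of provenance metadata (e.g. lexicon coverage).
#' @return a `cogspeech_features` object.
#' @export
feature_vector <- function(values, valid = NULL, meta = list()) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (is.null(valid)) valid <- is.finite(values)
  if (is.null(names(valid))) names(valid) <- names(values)
  stopifnot(identical(names(values), names(valid)))
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, meta = meta),
            class = "cogspeech_features")
}

#' @export
print.cogspeech_features <- function(x, ...) {
  cat(sprintf("<cogspeech_features: %d features, %d valid>\n",
              length(x$values), sum(x$valid)))
  print(utils::head(x$values, 10))
  invisible(x)
}

#' Merge feature vectors
#' @param ... `cogspeech_features` objects.
#' @return a single merged `cogspeech_features`.
#' @export
merge_features <- function(...) {
  parts <- list(...)
  feature_vector(
    do.call(c, lapply(parts, function(p) p$values)),
    do.call(c, lapply(parts, function(p) p$valid)),
    do.call(c, lapply(parts, function(p) p$meta))
  )
}

#' @export
as.data.frame.cogspeech_features <- function(x, ...) {
  as.data.frame(as.list(x$values), optional = TRUE)
}

#' Stack per-participant feature vectors into a data.frame
#' @param fv_list named list of `cogspeech_features` (names = participant ids).
#' @return data.frame with one row per participant, `participant_id` column
#'   first.
#' @export
feature_table <- function(fv_list) {
  stopifnot(length(fv_list) > 0)
  rows <- lapply(fv_list, function(f) as.data.frame(f))
  out <- do.call(rbind, rows)
  data.frame(participant_id = names(fv_list), out,
             row.names = NULL, check.names = FALSE)
}
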