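# Model persistence. The saved object is self-describing: vocabulary,
# SVM weights, full configuration and the stop-word-list hash travel with
# it, and a reloaded model yields identical predictions.

#' Save a fitted status model
#'
#' @param model A `status_model`.
#' @param path Output path (RDS).
#' @return `path`, invisibly.
#' @export
save_status_model <- function(model, path) {
  if (!inherits(model, "status_model")) abort("Not a status_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a saved status model
#'
#' @param path Path written by [save_status_model()].
#' @return The `status_model`.
#' @export
load_status_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such model file: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "status_model")) {
    abort(sprintf("%s does not contain a status_model", path))
  }
  model
}
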