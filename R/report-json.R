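## JSON report: stable documented key schema, machine-readable.

#' Write the JSON report
#'
#' Serializes the report model from [finalize_stats()] with a stable key
#' order (`summary`, `pre_filtering`, `post_filtering`,
#' `duplication_histogram`, `coverage`, `bed_regions` when a BED was
#' given, `options`, `version`). Duplication-histogram keys are cluster
#' sizes as strings in ascending order. Undefined rates are JSON `null`.
#' The file round-trips losslessly through [jsonlite::fromJSON].
#'
#' @param model Report model from [finalize_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(model, path) {
  order <- c("summary", "pre_filtering", "post_filtering",
             "duplication_histogram", "coverage", "bed_regions",
             "options", "version")
  model <- model[intersect(order, names(model))]
  jsonlite::write_json(model, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

report_json_string <- function(model) {
  order <- c("summary", "pre_filtering", "post_filtering",
             "duplication_histogram", "coverage", "bed_regions",
             "options", "version")
  model <- model[intersect(order, names(model))]
  as.character(jsonlite::toJSON(model, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}
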