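# Table and configuration round-tripping. Numeric CSV fields are written
# at full precision (15 significant digits survive the round trip).

#' Write / read an AZ table as CSV
#'
#' @param az an `az_table`.
#' @param path file path.
#' @rdname az_csv
#' @return `write_az_csv` returns `path` invisibly; `read_az_csv` an
#'   `az_table`.
#' @export
write_az_csv <- function(az, path) {
  df <- as.data.frame(az)
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname az_csv
read_az_csv <- function(path) {
  az <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("true_class" %in% names(az))
    az$true_class <- factor(az$true_class,
                            levels = c("silent", "spont_only", "active"))
  class(az) <- c("az_table", "data.frame")
  az
}

#' Write / read an event list as CSV
#'
#' @param events an `event_list` or `event_truth`.
#' @param path file path.
#' @rdname events_csv
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   the data.frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(format_full(as.data.frame(events)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname events_csv
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ev) <- c("event_list", "data.frame")
  ev
}

# Format numeric columns at full precision for lossless CSV round trips.
#' @noRd
format_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- sprintf("%.15g", df[[j]])
  }
  df
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' @param path configuration file; `.json` parsed with jsonlite,
#'   everything else with yaml.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Write a pipeline run configuration as YAML
#'
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
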