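#' Read and write flight telemetry CSV
#'
#' Telemetry files use the columns `t_s`, `lat_deg`, `lon_deg`,
#' `alt_ft_agl`, `vspeed_ftmin`; the missed flag is carried in a `missed`
#' column (constant per file).
#'
#' @param trace A [flight_trace()].
#' @param path File path.
#' @return `read_telemetry` returns a [flight_trace()];
#'   `write_telemetry` returns `path` invisibly.
#' @export
write_telemetry <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t, lat_deg = trace$lat,
                              lon_deg = trace$lon, alt_ft_agl = trace$alt,
                              vspeed_ftmin = trace$vspeed,
                              missed = trace$missed),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path)
  flight_trace(df$t_s, df$lat_deg, df$lon_deg, df$alt_ft_agl,
               df$vspeed_ftmin, missed = isTRUE(df$missed[1]))
}

#' Read and write n-back trial logs as JSON lines
#'
#' One JSON object per trial with fields `day`, `block`, `trial`,
#' `n_level`, `position_correct`, `image_correct`.
#'
#' @param log Trial data frame (see [generate_nback_log()]).
#' @param path File path.
#' @return `read_nback_log` returns the trial data frame.
#' @export
write_nback_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_nback_log
#' @export
read_nback_log <- function(path) {
  rows <- lapply(readLines(path), function(l)
    as.data.frame(jsonlite::fromJSON(l)))
  do.call(rbind, rows)
}

#' Read and write fNIRS channel maps as JSON
#'
#' @param channel_map Data frame with `channel`, `source`, `detector`,
#'   `distance_cm`, `roi` (see [fnirs_channel_map()]).
#' @param path File path.
#' @return `read_channel_map` returns the channel-map data frame.
#' @export
write_channel_map <- function(channel_map, path) {
  writeLines(jsonlite::toJSON(channel_map, dataframe = "rows", pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname write_channel_map
#' @export
read_channel_map <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("channel", "source", "detector", "distance_cm", "roi")
  if (!all(need %in% names(df)))
    stop("channel map must provide: ", paste(need, collapse = ", "))
  df
}

#' Write ground-truth parameters of a synthetic study as YAML
#'
#' @param study A `synthetic_study`.
#' @param path File path.
#' @export
write_ground_truth <- function(study, path) {
  yaml::write_yaml(list(seed = study$design$seed,
                        subjects = split(study$truth, study$truth$subject)),
                   path)
  invisible(path)
}
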