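#' Coerce a track-like object to a fix data frame
#'
#' Accepts a `sim_track` or any data frame with `timestamp`, `x`, `y`
#' columns; checks that timestamps are strictly increasing with no
#' duplicates.
#'
#' @param track track-like object.
#' @return data frame of fixes ordered by time.
#' @export
as_track_df <- function(track) {
  fixes <- if (inherits(track, "sim_track")) track$fixes else track
  if (!is.data.frame(fixes) || !all(c("timestamp", "x", "y") %in% names(fixes)))
    stop("track must be a sim_track or a data frame with timestamp, x, y")
  if (!"animal_id" %in% names(fixes)) fixes$animal_id <- "unknown"
  if (is.unsorted(fixes$timestamp, strictly = FALSE))
    fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  if (anyDuplicated(fixes$timestamp)) stop("duplicate timestamps in track")
  rownames(fixes) <- NULL
  fixes
}

#' Write a track to delimited text
#'
#' Columns `animal_id,timestamp_iso8601,x_m,y_m[,true_state]`; timestamps in
#' UTC ISO-8601.
#'
#' @param track track-like object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  fixes <- as_track_df(track)
  out <- data.frame(
    animal_id = fixes$animal_id,
    timestamp_iso8601 = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x_m = fixes$x, y_m = fixes$y)
  if ("true_state" %in% names(fixes)) out$true_state <- fixes$true_state
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track from delimited text
#'
#' @param path file written by [write_track()] (or any CSV with columns
#'   `animal_id,timestamp_iso8601,x_m,y_m`).
#' @return track data frame with `animal_id`, `timestamp` (POSIXct UTC),
#'   `x`, `y` and, when present, `true_state`.
#' @export
read_track <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp_iso8601", "x_m", "y_m")
  if (!all(need %in% names(raw)))
    stop("track file must have columns ", paste(need, collapse = ", "))
  fixes <- data.frame(
    animal_id = raw$animal_id,
    timestamp = as.POSIXct(raw$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
    x = raw$x_m, y = raw$y_m, stringsAsFactors = FALSE)
  if ("true_state" %in% names(raw)) fixes$true_state <- raw$true_state
  as_track_df(fixes)
}

#' Write an imperviousness raster as plain text
#'
#' Cell values go to `path` as a whitespace-delimited grid (one text row per
#' raster row, southernmost row first); the extent and cell size go to a JSON
#' sidecar at `paste0(path, ".json")`.
#'
#' @param raster an `imperv_raster`.
#' @param path output path for the value grid.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "imperv_raster"))
  write.table(raster$values, path, row.names = FALSE, col.names = FALSE)
  meta <- list(xmin = raster$xmin, ymin = raster$ymin,
               cell_size = raster$cell_size,
               nrow = nrow(raster$values), ncol = ncol(raster$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an imperviousness raster written by [write_raster()]
#' @param path path to the value grid (sidecar expected at `path.json`).
#' @return an `imperv_raster`.
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(read.table(path, header = FALSE))
  dimnames(values) <- NULL
  stopifnot(nrow(values) == meta$nrow, ncol(values) == meta$ncol)
  structure(list(values = values, xmin = meta$xmin, ymin = meta$ymin,
                 cell_size = meta$cell_size),
            class = "imperv_raster")
}
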