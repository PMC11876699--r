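#' Write / read an event table as CSV
#'
#' Columns: `microtubule_id`, `end`, `onset_time` (s), `catastrophe_time`
#' (s, empty when censored), `censored`, `lifetime` (s), `speed` (um/min),
#' `seed_anchor` (um).
#'
#' @param events an `event_table`.
#' @param path file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns the data frame.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write a drift track as CSV (`frame`, `dx`, `dy`)
#' @param track a `drift_track`.
#' @param path file path.
#' @export
write_drift_track <- function(track, path) {
  utils::write.csv(as.data.frame(track)[, c("frame", "dx", "dy")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export an image stack as multipage TIFF
#'
#' Writes channels of a `kymograph` or `fov_image` (or a named list of
#' matrices) as one 32-bit float TIFF page per channel, with a JSON sidecar
#' recording the channel order and calibration. Requires the `tiff` and
#' `jsonlite` packages.
#'
#' @param x a `kymograph`, `fov_image`, or named list of matrices.
#' @param path output `.tif` path; the sidecar is `<path>.json`.
#' @export
write_image_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF export")
  channels <- if (is.list(x) && !is.null(x$channels)) x$channels else x
  mx <- max(unlist(lapply(channels, max)), 1)
  tiff::writeTIFF(lapply(channels, function(m) m / mx), path,
                  bits.per.sample = 32L)
  meta <- list(channels = names(channels), intensity_scale = mx)
  for (f in c("pixel_size", "frame_interval", "origin", "seed_extent"))
    if (!is.null(x[[f]])) meta[[f]] <- x[[f]]
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
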