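#' Construct a six-channel sensor recording
#'
#' A recording holds six synchronized inertial channels sampled at a fixed
#' rate -- triaxial acceleration (`acc_v`, `acc_ml`, `acc_ap`, in g) and
#' triaxial angular velocity (`gyr_v`, `gyr_ml`, `gyr_ap`, in degrees/s) --
#' together with task markers. All sample indices in markers (and in
#' segmentations derived from recordings) are 0-based and half-open:
#' a marker `[start, end)` covers samples `start .. end - 1`.
#'
#' @param channels numeric matrix (or data frame) with the six named
#'   channel columns, one row per sample.
#' @param sample_rate sampling rate in Hz.
#' @param markers data frame with columns `task`, `trial`, `start`, `end`
#'   (0-based half-open sample indices). May have zero rows.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(channels, sample_rate,
                             markers = empty_markers()) {
  channels <- as.matrix(as.data.frame(channels)[, intersect(
    colnames(as.data.frame(channels)), CHANNELS), drop = FALSE])
  missing <- setdiff(CHANNELS, colnames(channels))
  if (length(missing) > 0)
    stop_pdm(paste0("missing channel: ", paste(missing, collapse = ", ")),
             "pdm_io_error")
  channels <- channels[, CHANNELS, drop = FALSE]
  storage.mode(channels) <- "double"
  if (nrow(channels) < 2)
    stop_pdm("recording must contain at least 2 samples", "pdm_io_error")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 0)
    stop_pdm("sample_rate must be a positive number", "pdm_io_error")
  markers <- as.data.frame(markers)
  validate_markers(markers, nrow(channels))
  rec <- structure(list(channels = channels,
                        sample_rate = as.numeric(sample_rate),
                        markers = markers),
                   class = "sensor_recording")
  rec
}

empty_markers <- function() {
  data.frame(task = character(), trial = integer(),
             start = integer(), end = integer())
}

validate_markers <- function(markers, n) {
  need <- c("task", "trial", "start", "end")
  if (!all(need %in% names(markers)))
    stop_pdm("markers must have columns task, trial, start, end",
             "pdm_io_error")
  if (nrow(markers) == 0) return(invisible(TRUE))
  if (any(markers$start < 0) || any(markers$end > n))
    stop_pdm("marker window out of bounds", "pdm_io_error")
  if (any(markers$end <= markers$start))
    stop_pdm("marker window has non-positive length", "pdm_io_error")
  invisible(TRUE)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d samples @ %g Hz (%.1f s), %d marker(s)\n",
              nrow(x$channels), x$sample_rate,
              nrow(x$channels) / x$sample_rate, nrow(x$markers)))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$channels)

#' Write / read a recording as CSV plus a JSON marker sidecar
#'
#' The CSV holds columns `time_s` and the six channels; markers (and the
#' ground-truth segments, when present as the `ground_truth` attribute)
#' go to `<path without extension>_markers.json`. A write followed by a
#' read reproduces channels to full stored precision and markers exactly.
#'
#' @param rec a `sensor_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `sensor_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  n <- n_samples(rec)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate)
  df <- cbind(df, as.data.frame(rec$channels))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  side <- list(sample_rate = rec$sample_rate, markers = rec$markers)
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) side$ground_truth <- gt
  jsonlite::write_json(side, sidecar_path(path), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.[^./]+$", "", path), "_markers.json")
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df))
    stop_pdm("missing time_s column", "pdm_io_error")
  if (nrow(df) >= 2 && any(diff(df$time_s) <= 0))
    stop_pdm("non-monotone time column", "pdm_io_error")
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  markers <- as.data.frame(side$markers)
  if (nrow(markers) == 0) markers <- empty_markers()
  rec <- sensor_recording(df, side$sample_rate, markers)
  if (!is.null(side$ground_truth))
    attr(rec, "ground_truth") <- as.data.frame(side$ground_truth)
  rec
}

#' Extract the sub-recording of one task marker
#'
#' Returns the samples of the half-open marker window `[start, end)` as a
#' new recording whose marker is rebased to index 0.
#'
#' @param rec a `sensor_recording`.
#' @param task task id, e.g. `"tug"`.
#' @param trial trial number (default 1).
#' @return A `sensor_recording` of `end - start` samples.
#' @export
extract_task_window <- function(rec, task, trial = 1) {
  stopifnot(inherits(rec, "sensor_recording"))
  m <- rec$markers
  hit <- which(m$task == task & m$trial == trial)
  if (length(hit) != 1)
    stop_pdm(sprintf("no marker for task '%s' trial %d", task, trial),
             "pdm_io_error")
  start <- m$start[hit]; end <- m$end[hit]
  ch <- rec$channels[(start + 1):end, , drop = FALSE]
  out <- sensor_recording(
    ch, rec$sample_rate,
    data.frame(task = task, trial = trial, start = 0L,
               end = as.integer(end - start)))
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) {
    keep <- gt$start >= start & gt$end <= end
    g <- gt[keep, , drop = FALSE]
    g$start <- g$start - start
    g$end <- g$end - start
    attr(out, "ground_truth") <- g
  }
  out
}
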