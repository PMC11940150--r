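#' Segmentation parameters
#'
#' Thresholds for decomposing complex tasks into subtasks from integrated
#' angular velocity. Turns are detected on the vertical gyroscope (trunk
#' yaw), postural transitions on the trunk-pitch gyroscope channel
#' (mediolateral axis for a lower-back sensor; configurable). A candidate
#' region is opened where the smoothed absolute angular rate exceeds the
#' detection threshold, its boundaries are then extended outward to the
#' lower refinement threshold, and regions are kept when the integrated
#' angle exceeds the minimum angle.
#'
#' @param turn_rate_thresh yaw-rate detection threshold, degrees/s.
#' @param pitch_rate_thresh pitch-rate detection threshold, degrees/s.
#' @param refine_rate_thresh boundary refinement threshold, degrees/s.
#' @param turn_angle_min minimum net turn angle, degrees.
#' @param pitch_angle_min minimum net pitch excursion, degrees.
#' @param merge_gap_s adjacent regions closer than this are merged, s.
#' @param min_segment_s minimum segment duration, s.
#' @param smooth_s moving-average length for rate smoothing, s.
#' @param stillness_sd_g stillness threshold on the moving standard
#'   deviation of total dynamic acceleration, g.
#' @param stillness_window_s moving window for the stillness statistic, s.
#' @param pitch_channel gyroscope channel carrying trunk pitch.
#' @return A `seg_params` list.
#' @export
seg_params <- function(turn_rate_thresh = 15, pitch_rate_thresh = 20,
                       refine_rate_thresh = 2, turn_angle_min = 90,
                       pitch_angle_min = 20, merge_gap_s = 0.5,
                       min_segment_s = 0.3, smooth_s = 0.3,
                       stillness_sd_g = 0.06, stillness_window_s = 0.5,
                       pitch_channel = "gyr_ml") {
  structure(as.list(environment()), class = "seg_params")
}

#' Cumulative trunk yaw by trapezoidal integration
#'
#' Integrates an angular-velocity series (degrees/s) into cumulative
#' angle (degrees) with the trapezoid rule; the first element is 0.
#'
#' @param gyr angular velocity series, degrees/s.
#' @param sample_rate Hz.
#' @return Numeric series of cumulative degrees, same length as input.
#' @export
cumulative_yaw <- function(gyr, sample_rate) {
  n <- length(gyr)
  if (n < 2)
    stop_pdm("need at least 2 samples to integrate", "pdm_segmentation_error")
  c(0, cumsum((gyr[-1] + gyr[-n]) / 2) / sample_rate)
}

# Centered moving average (partial windows at the edges).
moving_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Centered moving standard deviation.
moving_sd <- function(x, w) {
  m1 <- moving_mean(x, w)
  m2 <- moving_mean(x^2, w)
  sqrt(pmax(m2 - m1^2, 0))
}

# Detect high-rate regions on an angular-velocity series: open where the
# smoothed |rate| exceeds `high`, extend to the raw |rate| falling below
# `refine`, merge across short gaps, keep regions with |integrated
# angle| >= angle_min and duration >= min duration. Returns 0-based
# half-open (start, end) rows.
detect_rate_regions <- function(rate, fs, high, refine, angle_min,
                                merge_gap_s, min_segment_s, smooth_s) {
  n <- length(rate)
  sm <- abs(moving_mean(rate, max(1L, as.integer(round(smooth_s * fs)))))
  core <- sm >= high
  if (!any(core)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  araw <- abs(rate)
  refined <- t(apply(runs, 1, function(rr) {
    s <- rr[1]; e <- rr[2]
    while (s > 1 && araw[s - 1] >= refine) s <- s - 1
    while (e < n && araw[e + 1] >= refine) e <- e + 1
    c(s, e)
  }))
  # merge regions separated by less than the merge gap
  gap <- as.integer(round(merge_gap_s * fs))
  merged <- refined[1, , drop = FALSE]
  if (nrow(refined) > 1) {
    for (i in 2:nrow(refined)) {
      last <- nrow(merged)
      if (refined[i, 1] - merged[last, 2] <= gap) {
        merged[last, 2] <- max(merged[last, 2], refined[i, 2])
      } else merged <- rbind(merged, refined[i, , drop = FALSE])
    }
  }
  keep <- apply(merged, 1, function(rr) {
    idx <- rr[1]:rr[2]
    ang <- sum((rate[idx][-1] + rate[idx][-length(idx)]) / 2) / fs
    abs(ang) >= angle_min && (rr[2] - rr[1] + 1) >= min_segment_s * fs
  })
  out <- merged[keep, , drop = FALSE]
  out <- cbind(start = out[, 1] - 1L, end = out[, 2])  # to 0-based half-open
  out
}

#' Detect turns from cumulative yaw
#'
#' Finds maximal windows in which the yaw rate stays high and the net
#' yaw change reaches the minimum turn angle; adjacent windows closer
#' than the merge gap are merged.
#'
#' @param yaw cumulative yaw series in degrees (from [cumulative_yaw()]).
#' @param sample_rate Hz.
#' @param params a [seg_params()].
#' @return Matrix with 0-based half-open `start`, `end` columns
#'   (possibly zero rows).
#' @export
detect_turns <- function(yaw, sample_rate, params = seg_params()) {
  n <- length(yaw)
  if (n < 2) return(matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("start", "end"))))
  rate <- c(yaw[2] - yaw[1], diff(yaw)) * sample_rate
  detect_rate_regions(rate, sample_rate, params$turn_rate_thresh,
                      params$refine_rate_thresh, params$turn_angle_min,
                      params$merge_gap_s, params$min_segment_s,
                      params$smooth_s)
}

#' Detect the sit-to-stand and stand-to-sit transitions
#'
#' Postural transitions are high-rate pulses on the trunk-pitch
#' gyroscope whose integrated angle exceeds the pitch threshold. By
#' protocol order, the first detected transition is labeled
#' `sit_to_stand` and the last `stand_to_sit`. Fewer than two candidates
#' is a segmentation failure.
#'
#' @param rec a task-window `sensor_recording` of a TUG-like task.
#' @param params a [seg_params()].
#' @return Data frame with rows `sit_to_stand` and `stand_to_sit`
#'   (columns `label`, `start`, `end`; 0-based half-open).
#' @export
detect_postural_transitions <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "sensor_recording"))
  rate <- rec$channels[, params$pitch_channel]
  fs <- rec$sample_rate
  reg <- detect_rate_regions(rate, fs, params$pitch_rate_thresh,
                             params$refine_rate_thresh,
                             params$pitch_angle_min,
                             params$merge_gap_s, params$min_segment_s,
                             params$smooth_s)
  if (nrow(reg) < 2)
    stop_pdm("segmentation failed: fewer than two postural transition candidates",
             "pdm_segmentation_error")
  data.frame(label = c("sit_to_stand", "stand_to_sit"),
             start = c(reg[1, "start"], reg[nrow(reg), "start"]),
             end = c(reg[1, "end"], reg[nrow(reg), "end"]))
}

#' Mask of non-stationary samples
#'
#' A sample is flagged stationary when the moving standard deviation of
#' total dynamic acceleration (root of the summed per-channel moving
#' variances of the three accelerometer axes) falls below the stillness
#' threshold.
#'
#' @param rec a `sensor_recording`.
#' @param params a [seg_params()].
#' @return Logical vector, `TRUE` for retained (moving) samples.
#' @export
remove_stationary <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "sensor_recording"))
  w <- max(2L, as.integer(round(params$stillness_window_s * rec$sample_rate)))
  v <- rowSums(vapply(ACC_CHANNELS, function(ch)
    moving_sd(rec$channels[, ch], w)^2, numeric(n_samples(rec))))
  sqrt(v) >= params$stillness_sd_g
}

#' Segment a complex task into labeled subtasks
#'
#' TUG and cognitive TUG windows yield the canonical ordered sequence
#' sit_to_stand, walk, turn, walk, turn, stand_to_sit: the two postural
#' transitions bound the trial, exactly two turns are expected between
#' them, and the gaps between labeled segments become walking segments
#' after trimming stationary samples at their edges. A 32-foot-walk
#' window yields walking segments (any detected turns removed). Any
#' structural mismatch raises a segmentation failure so the recording
#' can be excluded.
#'
#' @param rec a task-window `sensor_recording`.
#' @param task `"tug"`, `"cogtug"` or `"walk32ft"`.
#' @param params a [seg_params()].
#' @param trial trial number carried into the result.
#' @return A `segmented_task`: list with `task`, `trial` and a
#'   `segments` data frame (`label`, `start`, `end`, 0-based half-open).
#' @export
segment_task <- function(rec, task, params = seg_params(), trial = 1L) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!task %in% c("tug", "cogtug", "walk32ft"))
    stop_pdm(paste0("segmentation is defined for complex tasks only, not ", task),
             "pdm_segmentation_error")
  fs <- rec$sample_rate
  moving <- remove_stationary(rec, params)
  if (task == "walk32ft") {
    yaw <- cumulative_yaw(rec$channels[, "gyr_v"], fs)
    turns <- detect_turns(yaw, fs, params)
    keep <- moving
    for (i in seq_len(nrow(turns)))
      keep[(turns[i, "start"] + 1):turns[i, "end"]] <- FALSE
    segs <- runs_to_segments(keep, fs, params$min_segment_s, "walk")
    if (nrow(segs) == 0)
      stop_pdm("segmentation failed: no walking segment found",
               "pdm_segmentation_error")
  } else {
    trans <- detect_postural_transitions(rec, params)
    yaw <- cumulative_yaw(rec$channels[, "gyr_v"], fs)
    turns <- detect_turns(yaw, fs, params)
    # keep only turns strictly between the two transitions
    turns <- turns[turns[, "start"] >= trans$end[1] &
                   turns[, "end"] <= trans$start[2], , drop = FALSE]
    if (nrow(turns) != 2)
      stop_pdm(sprintf(
        "segmentation failed: expected 2 turns between transitions, found %d",
        nrow(turns)), "pdm_segmentation_error")
    anchors <- data.frame(
      label = c("sit_to_stand", "turn", "turn", "stand_to_sit"),
      start = c(trans$start[1], turns[1, "start"], turns[2, "start"],
                trans$start[2]),
      end = c(trans$end[1], turns[1, "end"], turns[2, "end"],
              trans$end[2]))
    # Gaps between the anchors become walking segments when they hold
    # enough non-stationary samples; in the canonical TUG the walks sit
    # between sit-to-stand and turn 1 and between the two turns, while
    # the turn-2 -> stand-to-sit gap is empty (the second turn ends at
    # the chair).
    walks <- list()
    for (i in 1:3) {
      lo <- anchors$end[i]; hi <- anchors$start[i + 1]
      if (hi - lo < params$min_segment_s * fs) next
      idx <- (lo + 1):hi
      mv <- which(moving[idx])
      if (length(mv) < params$min_segment_s * fs) next
      walks[[length(walks) + 1]] <- data.frame(
        label = "walk", start = lo + mv[1] - 1L, end = lo + mv[length(mv)])
    }
    segs <- rbind(anchors, do.call(rbind, walks))
    segs <- segs[order(segs$start), , drop = FALSE]
    if (!identical(segs$label[1], "sit_to_stand") ||
        !identical(segs$label[nrow(segs)], "stand_to_sit") ||
        sum(segs$label == "turn") != 2 || sum(segs$label == "walk") != 2)
      stop_pdm("segmentation failed: non-canonical segment structure",
               "pdm_segmentation_error")
  }
  rownames(segs) <- NULL
  structure(list(task = task, trial = as.integer(trial),
                 segments = segs), class = "segmented_task")
}

runs_to_segments <- function(keep, fs, min_segment_s, label) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= min_segment_s * fs
  data.frame(label = rep(label, sum(ok)),
             start = starts[ok] - 1L, end = ends[ok])
}

#' @export
print.segmented_task <- function(x, ...) {
  cat(sprintf("<segmented_task> %s trial %d: %s\n", x$task, x$trial,
              paste(x$segments$label, collapse = " > ")))
  invisible(x)
}

#' Serialize / deserialize a segmentation as JSON
#' @param seg a `segmented_task`.
#' @param path JSON file path.
#' @return `write_segmentation` returns `path` invisibly.
#' @export
write_segmentation <- function(seg, path) {
  jsonlite::write_json(list(task = seg$task, trial = seg$trial,
                            segments = seg$segments),
                       path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(task = x$task, trial = as.integer(x$trial),
                 segments = as.data.frame(x$segments)),
            class = "segmented_task")
}
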