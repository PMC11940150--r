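# Fixed column schema of the participant-level feature table:
# one block of 549 window features per task segment, with four
# derivations (trial1, trial2, mean, difference) for the two-trial
# tasks. Returns a data.frame of column metadata in column order.
table_schema <- function() {
  wn <- window_feature_names()
  wm <- window_feature_meta()
  blocks <- list()
  add <- function(task, derivation, segpos, subtask) {
    data.frame(name = paste(task, derivation, segpos, wn, sep = "."),
               task = task, derivation = derivation, segpos = segpos,
               subtask = subtask, channel = wm$channel,
               domain = wm$domain)
  }
  tug_pos <- c("sit_to_stand", "walk_out", "turn1", "walk_return",
               "turn2", "stand_to_sit")
  tug_sub <- c("sit_to_stand", "walk", "turn", "walk", "turn",
               "stand_to_sit")
  blocks[[length(blocks) + 1]] <- add("walk32ft", "t1", "walk", "walk")
  blocks[[length(blocks) + 1]] <- add("stand_eo", "t1", "quiet_stance",
                                      "quiet_stance")
  blocks[[length(blocks) + 1]] <- add("stand_ec", "t1", "quiet_stance",
                                      "quiet_stance")
  for (task in c("tug", "cogtug"))
    for (deriv in c("t1", "t2", "mean", "diff"))
      for (i in seq_along(tug_pos))
        blocks[[length(blocks) + 1]] <- add(task, deriv, tug_pos[i],
                                            tug_sub[i])
  meta <- do.call(rbind, blocks)
  rownames(meta) <- NULL
  meta
}

# Features of the six TUG segments of one trial window (6 x 549 values),
# or NA-filled when the recording is absent or segmentation fails.
tug_trial_features <- function(rec, task, fspec, params) {
  nw <- length(window_feature_names())
  if (is.null(rec)) return(rep(NA_real_, 6 * nw))
  rec <- lowpass_filter(rec, fspec)
  seg <- tryCatch(segment_task(rec, task, params),
                  pdm_segmentation_error = function(e) NULL)
  if (is.null(seg)) return(rep(NA_real_, 6 * nw))
  fs <- rec$sample_rate
  unlist(lapply(seq_len(6), function(i) {
    s <- seg$segments$start[i]; e <- seg$segments$end[i]
    window_features(rec$channels[(s + 1):e, , drop = FALSE], fs)
  }), use.names = FALSE)
}

#' Assemble the participant-level feature table
#'
#' Runs signal conditioning, segmentation and the full feature registry
#' for every participant of a cohort: the six TUG/cogTUG subtask
#' segments of each trial, the longest walking segment of the 32-foot
#' walk, and the whole 20 s window of each stance task. For the
#' two-trial tasks the table carries four derivations of every base
#' feature: trial 1, trial 2, their mean and their difference
#' (trial1 - trial2). Missing recordings or failed segmentations leave
#' `NA` cells (later imputed by [preprocess_table()]).
#'
#' @param cohort a `pdm_cohort`.
#' @param fspec a [filter_spec()] applied to every recording.
#' @param params segmentation parameters.
#' @return A `feature_table`: list with `values` (participants x
#'   features numeric matrix), `meta` (column metadata: task,
#'   derivation, subtask, channel, domain), `participants`, `labels`.
#' @export
assemble_feature_table <- function(cohort, fspec = filter_spec(),
                                   params = seg_params()) {
  stopifnot(inherits(cohort, "pdm_cohort"))
  meta <- table_schema()
  nw <- length(window_feature_names())
  n <- length(cohort$participants)
  values <- matrix(NA_real_, n, nrow(meta))
  colnames(values) <- meta$name
  simple_block <- function(rec, use_longest_walk, params, fspec) {
    if (is.null(rec)) return(rep(NA_real_, nw))
    rec <- lowpass_filter(rec, fspec)
    ch <- rec$channels
    if (use_longest_walk) {
      seg <- tryCatch(segment_task(rec, "walk32ft", params),
                      pdm_segmentation_error = function(e) NULL)
      if (is.null(seg)) return(rep(NA_real_, nw))
      lens <- seg$segments$end - seg$segments$start
      i <- which.max(lens)
      ch <- ch[(seg$segments$start[i] + 1):seg$segments$end[i], ,
               drop = FALSE]
    }
    window_features(ch, rec$sample_rate)
  }
  for (i in seq_len(n)) {
    p <- cohort$participants[[i]]
    row <- c(
      simple_block(p$recordings[["walk32ft_1"]], TRUE, params, fspec),
      simple_block(p$recordings[["stand_eo_1"]], FALSE, params, fspec),
      simple_block(p$recordings[["stand_ec_1"]], FALSE, params, fspec))
    for (task in c("tug", "cogtug")) {
      t1 <- tug_trial_features(p$recordings[[paste0(task, "_1")]], task,
                               fspec, params)
      t2 <- tug_trial_features(p$recordings[[paste0(task, "_2")]], task,
                               fspec, params)
      row <- c(row, t1, t2, (t1 + t2) / 2, t1 - t2)
    }
    values[i, ] <- row
  }
  structure(list(values = values, meta = meta,
                 participants = cohort_ids(cohort),
                 labels = cohort_labels(cohort)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d participants x %d features (%d tasks)\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$task))))
  invisible(x)
}

#' Restrict a feature table to one task's columns
#' @param table a `feature_table`.
#' @param task task id, e.g. `"tug"`.
#' @return A `feature_table` with only that task's columns.
#' @export
subset_task <- function(table, task) {
  keep <- table$meta$task %in% task
  if (!any(keep)) stop_pdm("no columns for the requested task",
                           "pdm_feature_error")
  structure(list(values = table$values[, keep, drop = FALSE],
                 meta = table$meta[keep, , drop = FALSE],
                 participants = table$participants,
                 labels = table$labels),
            class = "feature_table")
}

#' Preprocess a feature table: drop degenerate columns, impute medians
#'
#' Columns that are constant, or contain non-finite values, on the
#' fitting rows are dropped. Remaining missing cells (in all rows) are
#' imputed with the per-column median computed on the fitting rows
#' only, so the fitted state can be reused on held-out rows without
#' leakage.
#'
#' @param table a `feature_table`.
#' @param fit_rows integer indices of the rows used to fit the state
#'   (default: all rows).
#' @return List with `table` (processed `feature_table`, all rows) and
#'   `state` (kept column names + medians), reusable via
#'   [apply_preprocess()].
#' @export
preprocess_table <- function(table, fit_rows = seq_len(nrow(table$values))) {
  if (length(fit_rows) == 0)
    stop_pdm("fit_rows must be non-empty", "pdm_feature_error")
  scr <- cpp_col_screen(table$values[fit_rows, , drop = FALSE])
  keep <- scr[, 1] == 0 & scr[, 2] == 0
  if (!any(keep))
    stop_pdm("preprocessing dropped every column", "pdm_feature_error")
  med <- cpp_col_medians(table$values[fit_rows, keep, drop = FALSE])
  state <- list(keep = colnames(table$values)[keep], medians = med)
  out <- table
  out$values <- impute_block(table$values[, keep, drop = FALSE], med)
  out$meta <- table$meta[keep, , drop = FALSE]
  list(table = out, state = state)
}

impute_block <- function(V, med) {
  bad <- !is.finite(V)
  if (any(bad)) V[bad] <- med[col(V)[bad]]
  V
}

#' @rdname preprocess_table
#' @param state a fitted preprocessing state.
#' @export
apply_preprocess <- function(state, table) {
  miss <- setdiff(state$keep, colnames(table$values))
  if (length(miss) > 0)
    stop_pdm("table lacks columns required by the preprocessing state",
             "pdm_feature_error")
  out <- table
  idx <- match(state$keep, colnames(table$values))
  out$values <- impute_block(table$values[, idx, drop = FALSE],
                             state$medians)
  out$meta <- table$meta[idx, , drop = FALSE]
  out
}

#' Write / read a feature table as CSV plus JSON metadata sidecar
#' @param table a `feature_table`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(participant = table$participants,
                   label = table$labels)
  df <- cbind(df, as.data.frame(table$values))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(table$meta, paste0(path, ".meta.json"),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- as.data.frame(jsonlite::read_json(paste0(path, ".meta.json"),
                                            simplifyVector = TRUE))
  values <- as.matrix(df[, meta$name, drop = FALSE])
  structure(list(values = values, meta = meta,
                 participants = df$participant, labels = df$label),
            class = "feature_table")
}
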