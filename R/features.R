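# Per-trial facial-feature construction: synchronisation-flash detection,
# pre-stimulus window summaries of landmark tracks, and training-set
# z-scoring.

#' Construct a keypoint time series
#'
#' @param frame_time frame timestamps, seconds.
#' @param landmarks named list; each element a data frame / list with
#'   numeric `x`, `y` and `confidence` (in `[0, 1]`) of the same length as
#'   `frame_time`.
#' @param pupil_size optional pupil-size trace (arbitrary units), same
#'   length as `frame_time`.
#' @return a `keypoint_timeseries` object.
#' @export
keypoint_timeseries <- function(frame_time, landmarks, pupil_size = NULL) {
  n <- length(frame_time)
  stopifnot(length(landmarks) >= 1, !is.null(names(landmarks)))
  for (nm in names(landmarks)) {
    lm <- landmarks[[nm]]
    if (length(lm$x) != n || length(lm$y) != n || length(lm$confidence) != n) {
      stop_invalid("landmark '%s' tracks must match frame_time length %d",
                   nm, n)
    }
    if (any(lm$confidence < 0 | lm$confidence > 1, na.rm = TRUE)) {
      stop_invalid("landmark '%s' confidence must lie in [0, 1]", nm)
    }
  }
  if (!is.null(pupil_size) && length(pupil_size) != n) {
    stop_invalid("pupil_size must match frame_time length")
  }
  structure(list(frame_time = frame_time, landmarks = landmarks,
                 pupil_size = pupil_size),
            class = "keypoint_timeseries")
}

#' Detect synchronisation flashes in a luminance trace
#'
#' Threshold crossings are grouped into flashes (nominal width 32 ms; at
#' 60 Hz a flash spans about 2 frames). A burst of five flashes whose
#' onsets fall within one second marks the session start; isolated single
#' flashes after it mark trial starts.
#'
#' @param luminance numeric luminance series.
#' @param sampling_rate Hz.
#' @param threshold luminance level separating flash from background;
#'   default halfway between the minimum and maximum of the trace.
#' @return list with `session_start` (seconds, `NA` when no five-flash
#'   burst is found) and `trial_starts` (seconds of each single flash
#'   after the session start).
#' @export
detect_sync_flashes <- function(luminance, sampling_rate,
                                threshold = NULL) {
  if (length(luminance) == 0) stop_invalid("luminance must be nonempty")
  if (is.null(threshold)) {
    threshold <- (max(luminance) + min(luminance)) / 2
  }
  high <- luminance > threshold
  if (!any(high)) {
    return(list(session_start = NA_real_, trial_starts = numeric(0)))
  }
  r <- rle(high)
  ends <- cumsum(r$lengths)
  onsets_idx <- (ends - r$lengths + 1L)[r$values]
  onsets <- (onsets_idx - 1) / sampling_rate
  n <- length(onsets)
  session_start <- NA_real_
  burst_end <- 0L
  if (n >= 5) {
    for (i in seq_len(n - 4L)) {
      if (onsets[i + 4L] - onsets[i] <= 1) {
        session_start <- onsets[i]
        burst_end <- i + 4L
        break
      }
    }
  }
  if (is.na(session_start)) {
    return(list(session_start = NA_real_, trial_starts = numeric(0)))
  }
  trial_starts <- onsets[seq_len(n) > burst_end]
  list(session_start = session_start, trial_starts = trial_starts)
}

#' Build the per-trial facial-feature table
#'
#' For each trial, summarises the window of `window_ms` milliseconds
#' ending at the trial (stimulus) start: per landmark the median x and
#' median y position and the total velocity (mean per-frame Euclidean
#' displacement magnitude), plus the median pupil size. Frames whose
#' landmark confidence falls below `min_confidence` are dropped from that
#' landmark's medians; features left undefined after filtering are
#' imputed with the session-wide feature median, so the table never
#' contains missing values.
#'
#' @param kp a [keypoint_timeseries].
#' @param trial_starts stimulus-onset times, seconds.
#' @param window_ms pre-stimulus window length, milliseconds.
#' @param min_confidence landmark confidence cutoff.
#' @return data frame with one row per retained trial: `trial`, then per
#'   landmark `<name>_x`, `<name>_y`, `<name>_vel`, then `pupil` when a
#'   pupil trace is present. Trials whose window starts before the
#'   recording are dropped with a warning. Column order is fixed by the
#'   landmark order of `kp`.
#' @export
build_trial_features <- function(kp, trial_starts, window_ms = 250,
                                 min_confidence = 0.6) {
  stopifnot(inherits(kp, "keypoint_timeseries"))
  window_s <- window_ms / 1000
  t0 <- min(kp$frame_time)
  ok <- trial_starts - window_s >= t0
  if (any(!ok)) {
    warning(sprintf("%d trial(s) dropped: pre-stimulus window precedes the recording",
                    sum(!ok)))
  }
  starts <- trial_starts[ok]
  lm_names <- names(kp$landmarks)
  has_pupil <- !is.null(kp$pupil_size)
  cols <- c(as.vector(t(outer(lm_names, c("_x", "_y", "_vel"), paste0))),
            if (has_pupil) "pupil")
  out <- matrix(NA_real_, length(starts), length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(starts)) {
    in_win <- kp$frame_time >= starts[i] - window_s &
      kp$frame_time < starts[i]
    for (nm in lm_names) {
      lm <- kp$landmarks[[nm]]
      conf_ok <- in_win & lm$confidence >= min_confidence
      if (any(conf_ok)) {
        out[i, paste0(nm, "_x")] <- median(lm$x[conf_ok])
        out[i, paste0(nm, "_y")] <- median(lm$y[conf_ok])
      }
      # velocity over the confident frames of the window, in order
      idx <- which(conf_ok)
      if (length(idx) >= 2) {
        dx <- diff(lm$x[idx])
        dy <- diff(lm$y[idx])
        out[i, paste0(nm, "_vel")] <- mean(sqrt(dx^2 + dy^2))
      }
    }
    if (has_pupil && any(in_win)) {
      out[i, "pupil"] <- median(kp$pupil_size[in_win], na.rm = TRUE)
    }
  }
  # impute remaining gaps with the session-wide feature median
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (any(miss)) out[miss, j] <- median(out[, j], na.rm = TRUE)
  }
  data.frame(trial = which(ok), out, check.names = FALSE)
}

#' Z-score the pupil column with training-set statistics
#'
#' The pupil column is replaced by `(value - train mean) / train sd`,
#' where the statistics are computed on the training rows only and the
#' same transform is applied to held-out rows.
#'
#' @param table a feature table with a `pupil` column.
#' @param train_rows row indices of the training set.
#' @param column column to transform (default `"pupil"`).
#' @return list with `table` (transformed) and `mean`, `sd` (the training
#'   statistics applied).
#' @export
zscore_pupil <- function(table, train_rows, column = "pupil") {
  if (!column %in% names(table)) stop_invalid("no '%s' column", column)
  if (length(train_rows) == 0) stop_invalid("train_rows must be nonempty")
  mu <- mean(table[[column]][train_rows])
  sigma <- sd(table[[column]][train_rows])
  if (!is.finite(sigma) || sigma == 0) {
    stop_invalid("training %s standard deviation is zero", column)
  }
  table[[column]] <- (table[[column]] - mu) / sigma
  list(table = table, mean = mu, sd = sigma)
}

#' Z-score every feature column with training-set statistics
#'
#' Applies the same training-statistics transform as [zscore_pupil] to all
#' feature columns, so regression weights are comparable across features.
#'
#' @param table a feature table.
#' @param train_rows row indices of the training set.
#' @param exclude columns left untouched (identifiers, labels).
#' @return list with `table`, `means`, `sds`.
#' @export
zscore_features <- function(table, train_rows,
                            exclude = c("trial", "session", "outcome", "rt",
                                        "state_true", "is_padding")) {
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                  exclude)
  means <- sds <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    res <- zscore_pupil(table, train_rows, column = cl)
    table <- res$table
    means[cl] <- res$mean
    sds[cl] <- res$sd
  }
  list(table = table, means = means, sds = sds)
}
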