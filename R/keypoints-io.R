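# Pose-keypoint CSV input/output in the common three-header-row dialect
# (rows: scorer, bodyparts, coords; per landmark the columns x, y,
# likelihood).

#' Read a pose-keypoint CSV
#'
#' Parses the three-header-row pose-estimation CSV dialect: the first
#' three rows name the scorer, the body part and the coordinate
#' (`x`/`y`/`likelihood`) of every column, the first column is the frame
#' index, and each subsequent row is one video frame. Frame indices are
#' converted to seconds via `frame_rate`.
#'
#' @param path CSV path.
#' @param frame_rate video frame rate, Hz.
#' @param pupil_column optional name of a landmark whose `x` column holds
#'   a precomputed scalar pupil size (consumed as `pupil_size`, not as a
#'   landmark).
#' @return a [keypoint_timeseries].
#' @export
read_keypoints <- function(path, frame_rate = 60, pupil_column = NULL) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(raw) < 4) stop_invalid("keypoint CSV must have 3 header rows plus data")
  if (tolower(raw[1, 1]) != "scorer") {
    stop_invalid("malformed header: row 1 must start with 'scorer', got '%s'",
                 raw[1, 1])
  }
  if (tolower(raw[2, 1]) != "bodyparts") {
    stop_invalid("malformed header: row 2 must start with 'bodyparts', got '%s'",
                 raw[2, 1])
  }
  if (tolower(raw[3, 1]) != "coords") {
    stop_invalid("malformed header: row 3 must start with 'coords', got '%s'",
                 raw[3, 1])
  }
  bodyparts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  if (!all(coords %in% c("x", "y", "likelihood"))) {
    stop_invalid("coords row entries must be x, y or likelihood")
  }
  data <- raw[-(1:3), , drop = FALSE]
  num <- suppressWarnings(
    vapply(seq_len(ncol(data)), function(j) as.numeric(data[[j]]),
           numeric(nrow(data))))
  num <- matrix(num, nrow = nrow(data))
  bad <- which(is.na(num) & data != "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_invalid("non-numeric cell at data row %d, column %d",
                 bad[1, 1], bad[1, 2])
  }
  frame_idx <- num[, 1]
  frame_time <- frame_idx / frame_rate
  landmarks <- list()
  for (bp in unique(bodyparts)) {
    sel <- which(bodyparts == bp) + 1L  # offset for the frame column
    part <- list()
    for (k in seq_along(sel)) {
      part[[coords[sel[k] - 1L]]] <- num[, sel[k]]
    }
    if (is.null(part$x) || is.null(part$y) || is.null(part$likelihood)) {
      stop_invalid("landmark '%s' must provide x, y and likelihood columns", bp)
    }
    landmarks[[bp]] <- list(x = part$x, y = part$y,
                            confidence = part$likelihood)
  }
  pupil <- NULL
  if (!is.null(pupil_column)) {
    if (!pupil_column %in% names(landmarks)) {
      stop_invalid("pupil_column '%s' not found among landmarks", pupil_column)
    }
    pupil <- landmarks[[pupil_column]]$x
    landmarks[[pupil_column]] <- NULL
  }
  keypoint_timeseries(frame_time, landmarks, pupil_size = pupil)
}

#' Write a keypoint time series in the three-header-row CSV dialect
#'
#' @param kp a [keypoint_timeseries].
#' @param path output CSV path.
#' @param frame_rate Hz, used to convert times back to frame indices.
#' @param scorer scorer name written in the first header row.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(kp, path, frame_rate = 60, scorer = "facestates") {
  stopifnot(inherits(kp, "keypoint_timeseries"))
  lm_names <- names(kp$landmarks)
  header1 <- c("scorer", rep(scorer, 3 * length(lm_names)))
  header2 <- c("bodyparts", rep(lm_names, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(lm_names)))
  block <- do.call(cbind, lapply(kp$landmarks, function(lm) {
    cbind(lm$x, lm$y, lm$confidence)
  }))
  frames <- round(kp$frame_time * frame_rate)
  body <- cbind(frames, block)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  lines <- apply(body, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  writeLines(lines, con)
  invisible(path)
}
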