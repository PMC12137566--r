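# Reaction-time extraction from lateral movement trajectories by
# sliding-window linear regression: a line fitted on one window is
# extrapolated onto the next; a drop in the out-of-window R^2 marks a
# deviation from straight-line movement, i.e. the onset of a directed
# turn. Candidates from several window sizes are fused with a time-decay
# weighting that favours the earliest consistent deviation.

#' Sliding-window extrapolation R-squared series
#'
#' For each position i, a line is fitted to window i (`n_w` samples) and
#' evaluated on the immediately following window of the same size; the
#' returned value is `1 - SS_res/SS_tot` computed on that second window
#' (so a perfectly linear continuation scores 1 and a deviation scores
#' low, possibly far below 0).
#'
#' The denominator is padded with `regularize * n_w` times the variance
#' of the globally detrended series. The raw ratio is scale-free in the
#' window-local noise, so without the pad any segment of noise produces
#' dips as deep as a genuine turn; the pad makes a dip register only
#' when the deviation is substantial at the scale of the trajectory's
#' overall movement, which is what a directed reaction is. Detrending
#' keeps the series exactly invariant under adding a constant offset or
#' a global linear trend.
#'
#' @param lateral numeric series of lateral positions.
#' @param n_w window size in samples (the series must have at least
#'   `2 * n_w` samples).
#' @param regularize denominator pad as a fraction of the detrended
#'   series variance per sample; 0 recovers the textbook ratio.
#' @return numeric vector of length `length(lateral) - 2*n_w + 1`;
#'   positions where the (padded) denominator is zero are `NA`
#'   (undefined) and excluded from the downstream peak search.
#' @export
windowed_r2 <- function(lateral, n_w, regularize = 0.02) {
  n <- length(lateral)
  n_w <- as.integer(n_w)
  if (n_w < 2) stop_invalid("n_w must be >= 2 samples")
  if (n < 2 * n_w) stop_invalid("series must have at least 2 * n_w samples")
  if (regularize < 0) stop_invalid("regularize must be >= 0")
  n_out <- n - 2L * n_w + 1L
  out <- numeric(n_out)
  idx_fit <- seq_len(n_w)
  xbar <- mean(idx_fit)
  sxx <- sum((idx_fit - xbar)^2)
  idx_eval <- (n_w + 1):(2 * n_w)
  # variance of the series after removing its global linear trend
  tt <- seq_len(n)
  trend_fit <- stats::lm.fit(cbind(1, tt), lateral)
  gvar <- sum(trend_fit$residuals^2) / max(1, n - 2)
  # an exactly (affinely) linear series leaves only rounding residue
  if (gvar <= 1e-20 * (mean(lateral^2) + 1)) gvar <- 0
  pad <- regularize * n_w * gvar
  for (i in seq_len(n_out)) {
    yfit <- lateral[i:(i + n_w - 1L)]
    slope <- sum((idx_fit - xbar) * (yfit - mean(yfit))) / sxx
    intercept <- mean(yfit) - slope * xbar
    yobs <- lateral[(i + n_w):(i + 2L * n_w - 1L)]
    pred <- intercept + slope * idx_eval
    ss_tot <- sum((yobs - mean(yobs))^2) + pad
    out[i] <- if (ss_tot == 0) NA_real_ else 1 - sum((yobs - pred)^2) / ss_tot
  }
  out
}

# Plateau-aware local maxima of a series (NA treated as -Inf, never peaks).
local_maxima <- function(x) {
  x[is.na(x)] <- -Inf
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peaks <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next  # edges cannot be interior maxima
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L] &&
        is.finite(r$values[j])) {
      # representative index: middle of the plateau
      peaks <- c(peaks, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  peaks
}

# Prominence of a peak: its height above the higher of the two flanking
# minima, where each flank extends until a strictly higher value (or the
# series edge) is reached.
peak_prominence <- function(x, peak) {
  x[is.na(x)] <- -Inf
  n <- length(x)
  h <- x[peak]
  left_min <- h
  i <- peak - 1L
  while (i >= 1L && x[i] <= h) {
    if (x[i] < left_min) left_min <- x[i]
    i <- i - 1L
  }
  right_min <- h
  i <- peak + 1L
  while (i <= n && x[i] <= h) {
    if (x[i] < right_min) right_min <- x[i]
    i <- i + 1L
  }
  h - max(left_min, right_min)
}

#' Candidate deviation points from an R-squared series
#'
#' Local maxima of the sign-reversed series `-r2` are retained if their
#' prominence (peak height above the higher of its flanking minima,
#' bounded by neighbouring higher peaks) reaches `lambda0` times the
#' series' dynamic range. The extrapolation R-squared is unbounded below,
#' so prominence is only meaningful on the scale of the series itself: a
#' genuine deviation dwarfs the fluctuation floor, making the candidate
#' set insensitive to the exact threshold.
#'
#' @param r2 R-squared series from [windowed_r2] (may contain `NA`).
#' @param lambda0 minimum prominence as a fraction of the dynamic range
#'   of `-r2`, >= 0.
#' @return integer indices into `r2`; an empty result is a valid outcome.
#' @export
find_candidates <- function(r2, lambda0 = 0.05) {
  if (length(r2) == 0) stop_invalid("r2 series must be nonempty")
  neg <- -r2
  peaks <- local_maxima(neg)
  if (length(peaks) == 0) return(integer(0))
  rng <- diff(range(neg[is.finite(neg)]))
  if (!is.finite(rng) || rng == 0) return(integer(0))
  prom <- vapply(peaks, function(p) peak_prominence(neg, p), numeric(1))
  peaks[prom >= lambda0 * rng]
}

#' Fuse candidate points across window sizes into one reaction time
#'
#' Each window size contributes a weight track: a normal density of width
#' `sigma` centred on each of its candidate sample indices, truncated to a
#' vicinity of `halfwidth` samples, zero elsewhere. The reaction-time
#' index is the argmax of the summed weight track divided by the 1-based
#' sample index, so among equally supported candidates the earliest wins.
#'
#' @param candidates_by_window list (one element per window size) of
#'   candidate sample indices, on the scale of the original series.
#' @param sigma normal width in samples; scalar or one value per window.
#' @param n_samples length of the original series.
#' @param halfwidth vicinity radius in samples; default `3 * sigma`.
#' @return list with `rt_index` (NA when every candidate set is empty,
#'   signalling no directed reaction) and `weight_profile` (the summed
#'   weight track).
#' @export
fuse_windows <- function(candidates_by_window, sigma, n_samples,
                         halfwidth = NULL) {
  if (n_samples < 1) stop_invalid("n_samples must be >= 1")
  k <- length(candidates_by_window)
  sigma <- rep(sigma, length.out = k)
  if (any(sigma <= 0)) stop_invalid("sigma must be > 0")
  if (is.null(halfwidth)) halfwidth <- 3 * sigma
  halfwidth <- rep(halfwidth, length.out = k)
  x <- seq_len(n_samples)
  total <- numeric(n_samples)
  any_cand <- FALSE
  for (w in seq_len(k)) {
    cands <- candidates_by_window[[w]]
    if (length(cands) == 0) next
    any_cand <- TRUE
    track <- numeric(n_samples)
    for (cc in cands) {
      inside <- abs(x - cc) <= halfwidth[w]
      track[inside] <- track[inside] + dnorm(x[inside] - cc, sd = sigma[w])
    }
    total <- total + track
  }
  if (!any_cand) {
    return(list(rt_index = NA_integer_, weight_profile = total))
  }
  list(rt_index = which.max(total / x), weight_profile = total)
}

#' Detector configuration
#'
#' @param window_ms window sizes in milliseconds.
#' @param lambda0 minimum peak prominence on the `-R^2` series.
#' @param sigma_samples fusion kernel width in samples; `NA` means one
#'   quarter of each window size.
#' @param halfwidth_samples vicinity radius in samples; `NA` means
#'   `3 * sigma`.
#' @param min_displacement minimum net lateral displacement (difference
#'   between the means of the last and first half-second spans), in
#'   lateral task units, for the trajectory to count as containing a
#'   directed reaction at all; 0 disables the gate. Stimuli sit at a
#'   fixed lateral offset in the task geometry, so a genuine approach
#'   displaces the track by a substantial fraction of that offset,
#'   whereas postural drift does not.
#' @param rel_prominence candidates must reach this fraction of the
#'   most prominent deviation of their window's series; filters
#'   incidental slope changes that are minor next to the actual turn.
#'   0 disables the filter.
#' @param regularize denominator pad of the extrapolation R-squared
#'   (see [windowed_r2]).
#' @return a `detector_config` list.
#' @export
detector_config <- function(window_ms = c(100, 150, 200, 250),
                            lambda0 = 0.05, sigma_samples = NA,
                            halfwidth_samples = NA, min_displacement = 0.5,
                            rel_prominence = 0.5, regularize = 0.02) {
  if (any(window_ms <= 0)) stop_invalid("window sizes must be positive")
  if (lambda0 < 0) stop_invalid("lambda0 must be >= 0")
  if (!is.na(sigma_samples) && any(sigma_samples <= 0)) {
    stop_invalid("sigma_samples must be > 0")
  }
  if (min_displacement < 0) stop_invalid("min_displacement must be >= 0")
  if (rel_prominence < 0 || rel_prominence > 1) {
    stop_invalid("rel_prominence must lie in [0, 1]")
  }
  structure(list(window_ms = window_ms, lambda0 = lambda0,
                 sigma_samples = sigma_samples,
                 halfwidth_samples = halfwidth_samples,
                 min_displacement = min_displacement,
                 rel_prominence = rel_prominence, regularize = regularize),
            class = "detector_config")
}

#' Detect the reaction time of one trajectory
#'
#' Runs the sliding-window R-squared scan and prominence-filtered peak
#' search for each configured window size, fuses the candidates, and
#' converts the fused index to seconds from the trajectory start
#' (stimulus onset). Only the lateral track is used; forward movement is
#' ignored.
#'
#' @param traj a `trajectory` object (see [trajectory]).
#' @param config a [detector_config].
#' @return an `rt_result` list: `rt` (seconds, `NA` when no directed
#'   reaction was found), `rt_index`, `defined`, `candidates_by_window`,
#'   `r2_by_window`, `weight_profile`.
#' @export
detect_rt <- function(traj, config = detector_config()) {
  stopifnot(inherits(traj, "trajectory"))
  sr <- traj$sampling_rate
  n <- length(traj$lateral)
  windows <- pmax(2L, as.integer(round(config$window_ms / 1000 * sr)))
  if (n < 2 * max(windows)) {
    stop_invalid("trajectory (%d samples) shorter than twice the largest window (%d samples)",
                 n, max(windows))
  }
  sigma <- if (is.na(config$sigma_samples[1])) windows / 4 else
    rep(config$sigma_samples, length.out = length(windows))
  halfwidth <- if (is.na(config$halfwidth_samples[1])) 3 * sigma else
    rep(config$halfwidth_samples, length.out = length(windows))
  # gate: a directed reaction must displace the track substantially in
  # task units; displacement between the first and last half-second
  span <- min(max(max(windows), round(0.5 * sr)), floor(n / 2))
  displacement <- abs(mean(traj$lateral[(n - span + 1):n]) -
                        mean(traj$lateral[seq_len(span)]))
  moved <- displacement >= config$min_displacement
  r2_by_window <- list()
  cand_by_window <- list()
  for (w in seq_along(windows)) {
    nw <- windows[w]
    r2 <- windowed_r2(traj$lateral, nw, regularize = config$regularize)
    cand <- if (moved) find_candidates(r2, config$lambda0) else integer(0)
    if (length(cand) > 1 && config$rel_prominence > 0) {
      neg <- -r2
      neg[is.na(neg)] <- -Inf
      prom <- vapply(cand, function(p) peak_prominence(neg, p), numeric(1))
      cand <- cand[prom >= config$rel_prominence * max(prom)]
    }
    # an R^2 position i evaluates the window starting at sample i + n_w:
    # map candidates onto original-series sample indices
    key <- as.character(config$window_ms[w])
    r2_by_window[[key]] <- r2
    cand_by_window[[key]] <- cand + nw
  }
  fused <- fuse_windows(cand_by_window, sigma, n, halfwidth)
  idx <- fused$rt_index
  structure(
    list(rt = if (is.na(idx)) NA_real_ else traj$time[idx],
         rt_index = idx, defined = !is.na(idx),
         candidates_by_window = cand_by_window,
         r2_by_window = r2_by_window,
         weight_profile = fused$weight_profile),
    class = "rt_result")
}
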