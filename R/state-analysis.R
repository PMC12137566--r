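# Downstream state characterisation: transition structure, dwell times,
# state certainty, stochastic superiority, emission-histogram clustering,
# outcome decoding, facial template matching, and the trial-history
# (autoregressive) baseline.

#' Empirical state transition matrix
#'
#' Row-normalised bigram counts of consecutive state assignments.
#' Transitions that straddle a session boundary are excluded; a state with
#' no outgoing observed transitions gets a uniform row.
#'
#' @param states integer state sequence.
#' @param n_states total number of states S.
#' @param sessions optional session labels (same length); transitions
#'   across a label change are not counted.
#' @return S x S row-stochastic matrix.
#' @export
empirical_transition_matrix <- function(states, n_states,
                                        sessions = NULL) {
  n <- length(states)
  if (n == 0) stop_invalid("states must be nonempty")
  counts <- matrix(0, n_states, n_states)
  if (n > 1) {
    from <- states[-n]
    to <- states[-1]
    keep <- rep(TRUE, n - 1)
    if (!is.null(sessions)) {
      keep <- sessions[-n] == sessions[-1]
      keep[is.na(keep)] <- FALSE
    }
    for (i in which(keep)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  out <- matrix(1 / n_states, n_states, n_states)
  ok <- rs > 0
  out[ok, ] <- counts[ok, , drop = FALSE] / rs[ok]
  out
}

#' Per-state dwell times
#'
#' Lengths of the maximal runs of consecutive trials spent in each state.
#' Runs do not cross session boundaries.
#'
#' @param states integer state sequence.
#' @param sessions optional session labels; a label change ends the
#'   current run.
#' @return named list mapping each observed state to its run-length
#'   vector.
#' @export
dwell_times <- function(states, sessions = NULL) {
  n <- length(states)
  if (n == 0) stop_invalid("states must be nonempty")
  if (is.null(sessions)) sessions <- rep(1L, n)
  out <- list()
  for (seg in split(states, factor(sessions, levels = unique(sessions)))) {
    r <- rle(seg)
    for (i in seq_along(r$values)) {
      key <- as.character(r$values[i])
      out[[key]] <- c(out[[key]], r$lengths[i])
    }
  }
  out[order(as.numeric(names(out)))]
}

#' Normalised Kullback-Leibler state certainty
#'
#' `KL(p || uniform) / log S = (log S - H(p)) / log S`: 0 for a uniform
#' posterior row (all states equally likely), 1 for a one-hot row (a
#' single present state).
#'
#' @param posterior_row probability vector over states (sums to 1), or a
#'   T x S matrix of rows.
#' @return value(s) in `[0, 1]`.
#' @export
state_certainty_kl <- function(posterior_row) {
  if (is.matrix(posterior_row)) {
    return(apply(posterior_row, 1L, state_certainty_kl))
  }
  S <- length(posterior_row)
  if (S < 2) stop_invalid("certainty is undefined for a single state")
  if (abs(sum(posterior_row) - 1) > 1e-8) {
    stop_invalid("posterior row must sum to 1")
  }
  p <- posterior_row[posterior_row > 0]
  entropy <- -sum(p * log(p))
  (log(S) - entropy) / log(S)
}

#' Vargha-Delaney stochastic superiority
#'
#' The A statistic is the probability that a random draw from `a` exceeds
#' one from `b`, ties counted half, computed from midranks (the
#' Mann-Whitney U form). The folded measure `Omega = max(A, 1 - A)` lies
#' in `[0.5, 1]`: 0.5 for completely overlapping samples, 1 for complete
#' stochastic dominance.
#'
#' @param a,b numeric samples (both nonempty).
#' @return list with `A` and `omega`.
#' @export
vargha_delaney_omega <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop_invalid("both samples must be nonempty")
  ranks <- rank(c(a, b))  # midranks for ties
  rank_sum_a <- sum(ranks[seq_len(n_a)])
  U <- rank_sum_a - n_a * (n_a + 1) / 2
  A <- U / (n_a * n_b)
  list(A = A, omega = max(A, 1 - A))
}

#' Band label for a separability value
#'
#' Labels an Omega value with the conventional effect-size bands: small
#' (0.56, 0.64), medium (0.64, 0.71), high (>= 0.71); values below 0.56
#' are labelled negligible.
#'
#' @param omega values in `[0.5, 1]`.
#' @return character vector of band labels.
#' @export
omega_band <- function(omega) {
  cut(omega, breaks = c(-Inf, 0.56, 0.64, 0.71, Inf),
      labels = c("negligible", "small", "medium", "high"),
      right = FALSE)
}

#' Face separability table across states
#'
#' Computes the Vargha-Delaney Omega for every feature and every pair of
#' states, optionally per session.
#'
#' @param features trial x M feature matrix or data frame.
#' @param states per-trial state assignment.
#' @param sessions optional per-trial session labels; when given, Omega is
#'   computed within each session.
#' @return data frame with columns `feature`, `state_a`, `state_b`,
#'   (`session`,) `omega`, `band`.
#' @export
face_separability <- function(features, states, sessions = NULL) {
  features <- as.data.frame(features)
  st <- sort(unique(states))
  if (length(st) < 2) stop_invalid("need at least two states")
  if (is.null(sessions)) sessions <- rep(1L, length(states))
  rows <- list()
  for (sess in unique(sessions)) {
    in_sess <- sessions == sess
    for (f in names(features)) {
      for (i in seq_along(st)) {
        for (j in seq_along(st)) {
          if (j <= i) next
          a <- features[[f]][in_sess & states == st[i]]
          b <- features[[f]][in_sess & states == st[j]]
          if (length(a) == 0 || length(b) == 0) next
          om <- vargha_delaney_omega(a, b)$omega
          rows[[length(rows) + 1L]] <- data.frame(
            feature = f, state_a = st[i], state_b = st[j],
            session = sess, omega = om)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$band <- omega_band(out$omega)
  out
}

#' Freedman-Diaconis histograms on shared bins
#'
#' Bin width `2 * IQR * n^(-1/3)` is computed on the pooled sample and the
#' same edges are used for every group, so the histograms are directly
#' comparable; each histogram is normalised to sum to 1. A zero pooled
#' IQR falls back to `range / sqrt(n)` bins with a warning.
#'
#' @param values_by_state list of numeric vectors (one per state, each
#'   with at least 2 values).
#' @return list with `histograms` (states x bins matrix of probability
#'   masses), `breaks`, `bin_width`.
#' @export
state_emission_histograms <- function(values_by_state) {
  stopifnot(length(values_by_state) >= 1)
  lens <- lengths(values_by_state)
  if (any(lens < 2)) stop_invalid("each state needs at least 2 values")
  pooled <- unlist(values_by_state)
  n <- length(pooled)
  width <- 2 * IQR(pooled) * n^(-1 / 3)
  lo <- min(pooled)
  hi <- max(pooled)
  if (width <= 0 || !is.finite(width)) {
    warning("zero pooled IQR; falling back to range/sqrt(n) binning")
    width <- (hi - lo) / max(1, floor(sqrt(n)))
  }
  if (width <= 0) width <- 1  # all values identical
  n_bins <- max(1L, ceiling((hi - lo) / width))
  breaks <- lo + width * (0:n_bins)
  breaks[length(breaks)] <- max(breaks[length(breaks)], hi)
  H <- t(vapply(values_by_state, function(v) {
    h <- hist(v, breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }, numeric(n_bins)))
  rownames(H) <- names(values_by_state)
  list(histograms = H, breaks = breaks, bin_width = width)
}

#' Jensen-Shannon distance between two histograms
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms:
#' symmetric, zero iff the histograms are equal, and at most 1 (attained
#' for disjoint supports).
#'
#' @param p,q probability vectors on the same support (each sums to 1).
#' @return distance in `[0, 1]`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop_invalid("histogram supports must match")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop_invalid("histograms must each sum to 1")
  }
  m <- (p + q) / 2
  kl2 <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(b[nz])))
  }
  d2 <- 0.5 * kl2(p, m) + 0.5 * kl2(q, m)
  sqrt(max(0, min(d2, 1)))
}

# Pairwise JS distance matrix between the rows of a histogram matrix.
js_distance_matrix <- function(H) {
  S <- nrow(H)
  D <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j > i) D[i, j] <- D[j, i] <- js_distance(H[i, ], H[j, ])
    }
  }
  D
}

#' Merge states by hierarchical clustering of emission histograms
#'
#' Agglomerative clustering (average linkage) on the pairwise
#' Jensen-Shannon distance matrix, cut at `threshold`: states whose
#' distances fall within or below the threshold end up in the same group.
#'
#' @param histograms states x bins matrix of probability masses (shared
#'   bins; see [state_emission_histograms]).
#' @param threshold Jensen-Shannon distance below which states are deemed
#'   indistinguishable (typically a shuffle-surrogate percentile).
#' @return integer group label per state.
#' @export
cluster_states <- function(histograms, threshold) {
  S <- nrow(histograms)
  if (S < 2) stop_invalid("need at least 2 states to cluster")
  D <- js_distance_matrix(histograms)
  hc <- hclust(as.dist(D), method = "average")
  cutree(hc, h = threshold)
}

#' Cluster fitted states by their predicted emissions
#'
#' Builds Freedman-Diaconis histograms (shared edges) of each state's
#' predicted-emission series, forms the shuffle-surrogate null for the
#' Jensen-Shannon distance, and merges states below the surrogate
#' percentile with [cluster_states]. The surrogate shuffles one state's
#' predicted-emission series (destroying its temporal structure), splits
#' it into two halves, and measures the JS distance between the half
#' histograms; over many shuffles this is the sampling distribution of
#' the JS distance between histograms drawn from one and the same
#' underlying distribution.
#'
#' @param pred_by_state T x S matrix: each column a state's predicted
#'   emission on every trial.
#' @param n_shuffles surrogate shuffles.
#' @param percentile surrogate percentile used as merge threshold
#'   (the 90-99 band).
#' @param seed integer seed.
#' @param shuffle_state which state's series feeds the surrogate.
#' @return list with `groups`, `threshold`, `distances`, `surrogate`.
#' @export
cluster_states_by_emissions <- function(pred_by_state, n_shuffles = 500,
                                        percentile = 95, seed = NULL,
                                        shuffle_state = 1L) {
  pred_by_state <- as.matrix(pred_by_state)
  S <- ncol(pred_by_state)
  if (S < 2) stop_invalid("need at least 2 states")
  hs <- state_emission_histograms(
    lapply(seq_len(S), function(s) pred_by_state[, s]))
  series <- pred_by_state[, shuffle_state]
  half <- floor(length(series) / 2)
  breaks <- hs$breaks
  surrogate <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- sample(series)
      h1 <- hist(shuf[seq_len(half)], breaks = breaks, plot = FALSE)$counts
      h2 <- hist(shuf[(half + 1):length(series)], breaks = breaks,
                 plot = FALSE)$counts
      js_distance(h1 / sum(h1), h2 / sum(h2))
    }, numeric(1))
  })
  threshold <- unname(quantile(surrogate, percentile / 100))
  groups <- cluster_states(hs$histograms, threshold)
  list(groups = groups, threshold = threshold,
       distances = js_distance_matrix(hs$histograms), surrogate = surrogate)
}

#' Decode trial outcome from state probabilities
#'
#' L2-penalised multinomial logistic regression of the outcome labels on
#' the smoothed state probabilities (standardised), with k-fold
#' cross-validated balanced accuracy (mean per-class recall) against the
#' 1/n_classes chance level. The per-state, per-class weights are the
#' association read-out between states and outcomes.
#'
#' @param posteriors T x S matrix of smoothed state probabilities.
#' @param outcomes per-trial outcome labels (>= 2 classes present).
#' @param k cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param lambda L2 penalty; default `1/T`, i.e. unit penalty strength in
#'   the summed-loss convention.
#' @return list with `weights` (state x class matrix), `balanced_accuracy`,
#'   `chance`, `confusion`.
#' @export
decode_outcome <- function(posteriors, outcomes, k = 5, seed = NULL,
                           lambda = NULL) {
  posteriors <- as.matrix(posteriors)
  outcomes <- as.factor(as.character(outcomes))
  classes <- levels(outcomes)
  if (length(classes) < 2) stop_invalid("need at least 2 outcome classes")
  n <- nrow(posteriors)
  if (is.null(lambda)) lambda <- 1 / n
  if (all(apply(posteriors, 2L, var) == 0)) {
    # degenerate input (e.g. one state dominating every trial): an
    # intercept-only classifier predicting the majority class
    majority <- classes[which.max(table(outcomes))]
    confusion <- table(truth = outcomes,
                       predicted = factor(rep(majority, n),
                                          levels = classes))
    recalls <- diag(confusion) / pmax(1, rowSums(confusion))
    weights <- matrix(0, ncol(posteriors), length(classes),
                      dimnames = list(paste0("state_",
                                             seq_len(ncol(posteriors))),
                                      classes))
    return(list(weights = weights, balanced_accuracy = mean(recalls),
                chance = 1 / length(classes), confusion = confusion))
  }
  family <- if (length(classes) == 2) "binomial" else "multinomial"
  full <- glmnet::glmnet(posteriors, outcomes, family = family,
                         alpha = 0, lambda = lambda, standardize = TRUE)
  cf <- coef(full, s = lambda)
  weights <- if (is.list(cf)) {
    do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1]))
  } else {
    cbind(`0` = -as.numeric(cf)[-1], `1` = as.numeric(cf)[-1])
  }
  if (is.list(cf)) colnames(weights) <- names(cf) else
    colnames(weights) <- classes
  rownames(weights) <- paste0("state_", seq_len(ncol(posteriors)))

  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- factor(rep(classes[1], n), levels = classes)
  for (f in seq_len(k)) {
    hold <- folds == f
    if (length(unique(outcomes[!hold])) < length(classes)) next
    m <- tryCatch(
      glmnet::glmnet(posteriors[!hold, , drop = FALSE], outcomes[!hold],
                     family = family, alpha = 0, lambda = lambda,
                     standardize = TRUE),
      error = function(e) NULL)
    if (is.null(m)) {  # degenerate fold: majority-class fallback
      tab <- table(outcomes[!hold])
      pred[hold] <- factor(names(tab)[which.max(tab)], levels = classes)
      next
    }
    p <- predict(m, posteriors[hold, , drop = FALSE], s = lambda,
                 type = "class")
    pred[hold] <- factor(as.character(p), levels = classes)
  }
  confusion <- table(truth = outcomes, predicted = pred)
  recalls <- diag(confusion) / pmax(1, rowSums(confusion))
  list(weights = weights,
       balanced_accuracy = mean(recalls),
       chance = 1 / length(classes),
       confusion = confusion)
}

#' Single-trial state decoding by facial template matching
#'
#' The template of a state is the mean training feature vector of its
#' trials; each test trial is assigned to the template with the highest
#' Pearson correlation (scale-invariant similarity). Trials with zero
#' feature variance are skipped with a warning.
#'
#' @param features trial x M feature matrix.
#' @param state_labels per-trial state assignment.
#' @param train_idx indices of training trials (every state must appear).
#' @param test_idx indices of test trials; default the complement of
#'   `train_idx` (or the training trials themselves if that is empty).
#' @return list with `predicted` (state per test trial, `NA` for skipped
#'   trials), `accuracy`, `chance`, `templates`.
#' @export
template_match <- function(features, state_labels, train_idx,
                           test_idx = NULL) {
  features <- as.matrix(features)
  states <- sort(unique(state_labels[train_idx]))
  if (length(states) < 1) stop_invalid("training set must contain states")
  if (is.null(test_idx)) {
    test_idx <- setdiff(seq_len(nrow(features)), train_idx)
    if (length(test_idx) == 0) test_idx <- train_idx
  }
  templates <- t(vapply(states, function(s) {
    colMeans(features[train_idx[state_labels[train_idx] == s], ,
                      drop = FALSE])
  }, numeric(ncol(features))))
  rownames(templates) <- states
  predicted <- rep(NA_integer_, length(test_idx))
  skipped <- 0L
  for (i in seq_along(test_idx)) {
    v <- features[test_idx[i], ]
    if (sd(v) == 0) {
      skipped <- skipped + 1L
      next
    }
    sims <- apply(templates, 1L, function(tpl) {
      if (sd(tpl) == 0) return(-Inf)
      cor(v, tpl)
    })
    predicted[i] <- states[which.max(sims)]
  }
  if (skipped > 0) {
    warning(sprintf("%d zero-variance trial(s) skipped", skipped))
  }
  ok <- !is.na(predicted)
  accuracy <- mean(predicted[ok] == state_labels[test_idx][ok])
  list(predicted = predicted, accuracy = accuracy,
       chance = 1 / length(states), templates = templates)
}

#' Trial-history (autoregressive) baseline
#'
#' Refits the identical switching pipeline with a single predictor: the
#' previous trial's reaction time (0 for the first trial of each session,
#' which is excluded from scoring). Quantifies how much of the reaction
#' time is predictable from trial history alone, the bar the facial
#' features must beat.
#'
#' @param data trial data frame with `session` and `rt`.
#' @param n_states,alpha,beta,seed,n_iter,n_restarts EM settings.
#' @param k,reps time-blocked CV settings.
#' @return list with `fit` (on the full data), `cv` (a `cv_result` on the
#'   lagged dataset with first-of-session trials excluded from scoring),
#'   and `lagged_data`.
#' @export
fit_arhmm_baseline <- function(data, n_states = 1, alpha = 1, beta = 1,
                               seed = NULL, n_iter = 50, n_restarts = 3,
                               k = 5, reps = 1) {
  keep <- if (is.null(data$is_padding)) rep(TRUE, nrow(data)) else !data$is_padding
  data <- data[keep, , drop = FALSE]
  sessions <- split(data, factor(data$session, levels = unique(data$session)))
  lagged <- lapply(sessions, function(s) {
    if (nrow(s) < 2) stop_invalid("each session needs >= 2 trials")
    out <- data.frame(session = s$session, x_1 = c(0, head(s$rt, -1)),
                      rt = s$rt, is_padding = FALSE,
                      first_of_session = c(TRUE, rep(FALSE, nrow(s) - 1)))
    out
  })
  lagged <- do.call(rbind, c(lagged, list(make.row.names = FALSE)))
  scored <- lagged[!lagged$first_of_session, , drop = FALSE]
  fit <- fit_em(lagged, n_states, alpha = alpha, beta = beta,
                n_iter = n_iter, n_restarts = n_restarts, seed = seed,
                session_reset = "reset")
  cv <- time_blocked_cv(scored, n_states, alpha = alpha, beta = beta,
                        k = k, reps = reps, seed = seed, n_iter = n_iter,
                        n_restarts = n_restarts)
  list(fit = fit, cv = cv, lagged_data = lagged)
}
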