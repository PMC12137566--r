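# Train/test splitting, time-blocked cross-validation, hyperparameter
# search, state-number selection, shuffle surrogates, and the synthetic
# ground-truth recovery experiment.

#' Chronological train/test split per session
#'
#' Within each session the chronologically first `ratio` of trials form
#' the training set and the remainder the test set; the split is disjoint,
#' exhaustive and order-preserving. Sessions shorter than `min_trials` are
#' excluded with a warning.
#'
#' @param data a trial data frame with a `session` column.
#' @param ratio training fraction.
#' @param min_trials minimum session length retained.
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(data, ratio = 0.8, min_trials = 5) {
  stopifnot(ratio > 0, ratio < 1)
  sessions <- split(data, factor(data$session, levels = unique(data$session)))
  train <- test <- list()
  for (nm in names(sessions)) {
    s <- sessions[[nm]]
    if (nrow(s) < min_trials) {
      warning(sprintf("session '%s' has %d < %d trials; excluded",
                      nm, nrow(s), min_trials))
      next
    }
    n_train <- floor(ratio * nrow(s))
    train[[nm]] <- s[seq_len(n_train), , drop = FALSE]
    test[[nm]] <- s[(n_train + 1):nrow(s), , drop = FALSE]
  }
  if (length(train) == 0) stop_invalid("no session long enough to split")
  list(train = do.call(rbind, c(train, list(make.row.names = FALSE))),
       test = do.call(rbind, c(test, list(make.row.names = FALSE))))
}

# Contiguous fold boundaries: k blocks covering 1..n exactly once.
cv_fold_indices <- function(n, k) {
  stopifnot(k >= 2, n >= k)
  edges <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (edges[i] + 1):edges[i + 1])
}

#' Time-blocked cross-validation of an MSLR
#'
#' The (non-padding) training trials are cut into `k` contiguous,
#' chronologically ordered blocks; each block is held out once per
#' repetition while the model is fitted on the remaining trials (the gap
#' induces a chain reset). Repetitions differ only in the restart seeds.
#' Held-out performance is `R^2 = 1 - SS_res/SS_tot` of the predicted
#' reaction times on the held-out block.
#'
#' @param train a trial data frame.
#' @param n_states number of latent states fitted.
#' @param alpha,beta sticky transition pseudo-counts.
#' @param k number of contiguous folds.
#' @param reps repetitions (independent restart seeds).
#' @param seed integer seed.
#' @param n_iter,n_restarts EM settings per fold fit.
#' @return a `cv_result`: data frame `results` (fold, rep, r2), data
#'   frame `predictions` (per held-out trial: fold, rep, index, observed,
#'   predicted), and summary scalars `max_r2`, `q05_r2` (5th percentile),
#'   `mean_r2`.
#' @export
time_blocked_cv <- function(train, n_states, alpha = 1, beta = 1, k = 5,
                            reps = 5, seed = NULL, n_iter = 50,
                            n_restarts = 3) {
  keep <- if (is.null(train$is_padding)) rep(TRUE, nrow(train)) else !train$is_padding
  data <- train[keep, , drop = FALSE]
  n <- nrow(data)
  folds <- cv_fold_indices(n, k)
  X <- feature_matrix(data)
  rows <- list()
  preds <- list()
  for (rep_i in seq_len(reps)) {
    for (fold_i in seq_len(k)) {
      hold <- folds[[fold_i]]
      fit_data <- data[-hold, , drop = FALSE]
      # the removed block splits the remaining data into two chain segments;
      # original session boundaries are preserved
      fit_data$session <- paste0(
        fit_data$session,
        ifelse(seq_len(nrow(fit_data)) <= min(hold) - 1, "_pre", "_post"))
      fit <- fit_em(fit_data, n_states, alpha = alpha, beta = beta,
                    n_iter = n_iter, n_restarts = n_restarts,
                    seed = child_seed(seed, rep_i * 100 + fold_i),
                    session_reset = "reset")
      held_y <- data$rt[hold]
      if (var(held_y) == 0) {
        warning(sprintf("fold %d: degenerate held-out variance; skipped", fold_i))
        next
      }
      pred <- mslr_predict(fit$params, X[hold, , drop = FALSE], held_y)
      rows[[length(rows) + 1L]] <-
        data.frame(fold = fold_i, rep = rep_i,
                   r2 = r_squared(held_y, pred$predicted))
      preds[[length(preds) + 1L]] <-
        data.frame(fold = fold_i, rep = rep_i, index = hold,
                   observed = held_y, predicted = pred$predicted)
    }
  }
  results <- do.call(rbind, rows)
  predictions <- do.call(rbind, preds)
  structure(list(results = results, predictions = predictions,
                 max_r2 = max(results$r2),
                 q05_r2 = unname(quantile(results$r2, 0.05)),
                 mean_r2 = mean(results$r2),
                 n_states = n_states, k = k, reps = reps),
            class = "cv_result")
}

#' Select the number of states from a cross-validation curve
#'
#' Returns the state count with the largest finite difference
#' `R2(S) - R2(S - 1)` of the cross-validation performance curve, the
#' point of greatest marginal gain before the curve saturates. Ties break
#' toward the smaller state count.
#'
#' @param cv_curve named numeric vector of maximum CV R-squared per state
#'   count, defined on consecutive S starting at 1.
#' @return the selected state count S*.
#' @export
select_n_states <- function(cv_curve) {
  if (length(cv_curve) < 2) stop_invalid("cv_curve needs at least 2 points")
  s_vals <- as.integer(names(cv_curve))
  if (is.null(names(cv_curve)) || any(is.na(s_vals))) {
    s_vals <- seq_along(cv_curve)
  }
  if (any(diff(s_vals) != 1)) {
    stop_invalid("cv_curve must be defined on consecutive state counts")
  }
  diffs <- diff(cv_curve)
  s_vals[which.max(diffs) + 1L]
}

#' Search the sticky-transition hyperparameters
#'
#' Maximises the mean time-blocked cross-validation R-squared over the
#' concentration/stickiness plane with a pluggable sequential optimiser.
#' The default backend spends 70% of the budget on seeded uniform
#' exploration and the rest on Gaussian local refinement around the
#' incumbent; an alternative backend (e.g. an evolutionary strategy) can
#' be supplied as a function with the same signature.
#'
#' @param train trial data frame.
#' @param n_states number of latent states.
#' @param alpha_range,beta_range numeric length-2 search ranges.
#' @param n_trials evaluation budget.
#' @param seed integer seed; histories are reproducible given the seed.
#' @param backend `function(objective, alpha_range, beta_range, n_trials,
#'   seed)` returning a data frame with columns `alpha`, `beta`, `value`.
#' @param ... further arguments passed to [time_blocked_cv].
#' @return list with `alpha`, `beta`, `value` (the incumbent) and
#'   `history` (one row per evaluation).
#' @export
hyperparam_search <- function(train, n_states, alpha_range = c(0, 100),
                              beta_range = c(0, 100), n_trials = 100,
                              seed = NULL, backend = random_search_backend,
                              ...) {
  stopifnot(length(alpha_range) == 2, length(beta_range) == 2,
            alpha_range[1] <= alpha_range[2], beta_range[1] <= beta_range[2])
  extra <- list(...)
  objective <- function(alpha, beta) {
    cv <- do.call(time_blocked_cv,
                  c(list(train = train, n_states = n_states, alpha = alpha,
                         beta = beta, seed = child_seed(seed, 7)),
                    extra))
    cv$mean_r2
  }
  history <- backend(objective, alpha_range, beta_range, n_trials, seed)
  best <- history[which.max(history$value), ]
  list(alpha = best$alpha, beta = best$beta, value = best$value,
       history = history)
}

#' @rdname hyperparam_search
#' @param objective function of `(alpha, beta)` returning the value to
#'   maximise.
#' @export
random_search_backend <- function(objective, alpha_range, beta_range,
                                  n_trials, seed = NULL) {
  n_explore <- max(1L, ceiling(0.7 * n_trials))
  pts <- with_seed(seed, {
    explore <- data.frame(
      alpha = runif(n_explore, alpha_range[1], alpha_range[2]),
      beta = runif(n_explore, beta_range[1], beta_range[2]))
    explore
  })
  history <- pts
  history$value <- NA_real_
  for (i in seq_len(nrow(history))) {
    history$value[i] <- objective(history$alpha[i], history$beta[i])
  }
  n_refine <- n_trials - n_explore
  if (n_refine > 0) {
    props <- with_seed(child_seed(seed, 1), {
      sd_a <- diff(alpha_range) / 10
      sd_b <- diff(beta_range) / 10
      data.frame(da = rnorm(n_refine, sd = sd_a),
                 db = rnorm(n_refine, sd = sd_b))
    })
    for (i in seq_len(n_refine)) {
      inc <- history[which.max(history$value), ]
      a <- min(max(inc$alpha + props$da[i], alpha_range[1]), alpha_range[2])
      b <- min(max(inc$beta + props$db[i], beta_range[1]), beta_range[2])
      history <- rbind(history,
                       data.frame(alpha = a, beta = b,
                                  value = objective(a, b)))
    }
  }
  rownames(history) <- NULL
  history
}

#' Shuffle-surrogate performance threshold
#'
#' The model's predictions are computed once from the real test data;
#' the emissions are then shuffled uniformly `n_shuffles` times and each
#' shuffle is scored against those fixed predictions. The resulting
#' R-squared distribution is centred below zero (the predictions carry
#' variance that a shuffled target never matches, and only a finite-sample
#' correlation between the shuffling and the truth remains); its requested
#' percentile is the chance floor a real model performance must clear.
#'
#' @param params an [mslr_params] or `mslr_fit`.
#' @param test a trial data frame.
#' @param n_shuffles number of shuffles.
#' @param percentile percentile of the surrogate distribution (0-100).
#' @param seed integer seed.
#' @return list with `threshold`, the full `r2` distribution, and the
#'   model's `observed_r2` on the unshuffled emissions.
#' @export
surrogate_performance <- function(params, test, n_shuffles = 500,
                                  percentile = 99, seed = NULL) {
  if (inherits(params, "mslr_fit")) params <- params$params
  if (nrow(test) == 0) stop_invalid("test data must be nonempty")
  keep <- if (is.null(test$is_padding)) rep(TRUE, nrow(test)) else !test$is_padding
  test <- test[keep, , drop = FALSE]
  X <- feature_matrix(test)
  y <- test$rt
  pred <- mslr_predict(params, X, y)$predicted
  r2 <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      ys <- sample(y)
      r_squared(ys, pred)
    }, numeric(1))
  })
  list(threshold = unname(quantile(r2, percentile / 100)), r2 = r2,
       observed_r2 = r_squared(y, pred))
}

#' One-hot state-sequence correlation with optimal matching
#'
#' One-hot encodes two state sequences, computes the full pairwise Pearson
#' correlation matrix, and matches inferred to true states one-to-one by
#' maximum-weight assignment. Entries below `mask_threshold` are set to
#' `NA` in the masked matrix.
#'
#' @param true_states,inferred_states integer state sequences of equal
#'   length.
#' @param mask_threshold correlations at or below this value are masked.
#' @return list with `correlation` (S_true x S_inf), `assignment` (column
#'   matched to each true state), `diagonal` (matched correlations) and
#'   `masked` (the correlation matrix with sub-threshold entries `NA`).
#' @export
state_sequence_correlation <- function(true_states, inferred_states,
                                       mask_threshold = -Inf) {
  stopifnot(length(true_states) == length(inferred_states))
  s_true <- max(true_states)
  s_inf <- max(inferred_states)
  H_true <- one_hot_states(true_states, s_true)
  H_inf <- one_hot_states(inferred_states, s_inf)
  corr <- suppressWarnings(cor(H_true, H_inf))
  corr[is.na(corr)] <- 0  # states never visited give zero-variance columns
  assignment <- match_states(corr)
  diagonal <- corr[cbind(seq_len(s_true), assignment)]
  masked <- corr
  masked[masked <= mask_threshold] <- NA_real_
  list(correlation = corr, assignment = assignment, diagonal = diagonal,
       masked = masked)
}

# Null distribution of one-hot state-sequence correlations: shuffle the
# inferred sequence, correlate against the true one, pool all entries.
surrogate_state_correlation <- function(true_states, inferred_states,
                                        n_shuffles = 500, percentile = 99,
                                        seed = NULL) {
  H_true <- one_hot_states(true_states, max(true_states))
  vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      shuf <- sample(inferred_states)
      H_s <- one_hot_states(shuf, max(inferred_states))
      cc <- suppressWarnings(cor(H_true, H_s))
      cc[is.finite(cc)]
    }))
  })
  unname(quantile(vals, percentile / 100))
}

#' Synthetic ground-truth state-recovery experiment
#'
#' Simulates a dataset from a seeded ground-truth MSLR, deliberately
#' overfits the state count, merges redundant states by hierarchical
#' clustering of their predicted-emission histograms against a
#' shuffle-surrogate Jensen-Shannon threshold, refits with the selected
#' state count, and quantifies recovery as the optimally matched one-hot
#' state-sequence correlation (masking entries below the 99th-percentile
#' correlation surrogate).
#'
#' @param s_true ground-truth number of states.
#' @param s_fit deliberately large fitted state count.
#' @param n_trials,n_features simulated dataset size.
#' @param ar_coef predictor lag-1 autocorrelation.
#' @param alpha,beta sticky transition pseudo-counts (generation and fit).
#' @param emission_noise_sd ground-truth emission noise.
#' @param seed integer seed driving every random stage.
#' @param n_iter,n_restarts EM settings.
#' @param n_shuffles surrogate shuffle count.
#' @param merge_percentile percentile of the Jensen-Shannon surrogate used
#'   as merge threshold (the 90-99 band).
#' @param min_occupancy smallest fraction of trials a fitted state must
#'   dominate (argmax) to count as a behavioural state; states below it
#'   are overfitting residue (typically a handful of memorised trials)
#'   and are excluded from the clustering.
#' @return a `recovery_report`: list with `selected_n_states`, `groups`,
#'   `js_threshold`, `correlation` (matched, masked matrices and
#'   diagonal), `surrogate_correlation_threshold`, and the fitted models.
#' @export
recover_states_experiment <- function(s_true = 5, s_fit = 10,
                                      n_trials = 4000, n_features = 10,
                                      ar_coef = 0.3, alpha = 1, beta = 20,
                                      emission_noise_sd = 0.3, seed = NULL,
                                      n_iter = 50, n_restarts = 10,
                                      n_shuffles = 500,
                                      merge_percentile = 95,
                                      min_occupancy = 0.01) {
  truth_params <- make_ground_truth_params(
    s_true, n_features, alpha = alpha, beta = beta,
    emission_noise_sd = emission_noise_sd, seed = child_seed(seed, 1))
  X <- generate_facial_inputs(n_trials, n_features, ar_coef = ar_coef,
                              seed = child_seed(seed, 2))
  sim <- sample_mslr_dataset(truth_params, X, seed = child_seed(seed, 3))
  data <- sim$data

  # stage 1: overfit, then merge redundant states
  fit_over <- fit_em(data, s_fit, alpha = alpha, beta = beta,
                     n_iter = n_iter, n_restarts = n_restarts,
                     seed = child_seed(seed, 4))
  Xm <- feature_matrix(data)
  occupancy <- tabulate(fit_over$posterior$argmax_state, s_fit) / n_trials
  occupied <- which(occupancy >= min_occupancy)
  pred_by_state <- sweep(Xm %*% t(fit_over$params$weights), 2L,
                         fit_over$params$biases, `+`)
  clust <- cluster_states_by_emissions(
    pred_by_state[, occupied, drop = FALSE], n_shuffles = n_shuffles,
    percentile = merge_percentile, seed = child_seed(seed, 5))
  s_sel <- length(unique(clust$groups))

  # stage 2: refit at the selected state count and score recovery
  fit_sel <- fit_em(data, s_sel, alpha = alpha, beta = beta,
                    n_iter = n_iter, n_restarts = n_restarts,
                    seed = child_seed(seed, 6))
  corr_thr <- surrogate_state_correlation(
    sim$truth$state_sequence, fit_sel$posterior$argmax_state,
    n_shuffles = n_shuffles, percentile = 99, seed = child_seed(seed, 7))
  corr <- state_sequence_correlation(
    sim$truth$state_sequence, fit_sel$posterior$argmax_state,
    mask_threshold = corr_thr)

  structure(
    list(selected_n_states = s_sel, groups = clust$groups,
         occupied_states = occupied, occupancy = occupancy,
         js_threshold = clust$threshold, js_distances = clust$distances,
         correlation = corr, surrogate_correlation_threshold = corr_thr,
         min_matched_correlation = min(corr$diagonal),
         truth = sim$truth, data = data,
         fit_overcomplete = fit_over, fit_selected = fit_sel),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("State-recovery experiment: %d states selected (JS threshold %.3f)\n",
              x$selected_n_states, x$js_threshold))
  cat(sprintf("  matched one-hot correlations: min %.3f (surrogate 99th pct %.3f)\n",
              x$min_matched_correlation, x$surrogate_correlation_threshold))
  invisible(x)
}
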