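# Splitting, time-blocked cross-validation, state-number selection,
# hyperparameter search, surrogates, state matching.

test_that("the chronological split is per-session, disjoint, exhaustive", {
  fx <- make_recovery_fixture(100, seed = 1)
  d1 <- fx$sim$data
  d2 <- fx$sim$data
  d2$session <- 2L
  d2 <- d2[1:60, ]
  data <- rbind(d1, d2)
  sp <- split_train_test(data, ratio = 0.8)
  expect_identical(nrow(sp$train), 80L + 48L)
  expect_identical(nrow(sp$test), 20L + 12L)
  # within each session: order preserved, test is the chronological tail
  for (s in c(1L, 2L)) {
    tr <- sp$train[sp$train$session == s, ]
    te <- sp$test[sp$test$session == s, ]
    expect_true(max(tr$trial) < min(te$trial))
    full <- data[data$session == s, ]
    expect_identical(sort(c(tr$trial, te$trial)), full$trial)
    expect_identical(max(te$trial), max(full$trial))
  }
  # sessions too short to split are dropped with a warning
  tiny <- d1[1:3, ]
  tiny$session <- 3L
  expect_warning(sp2 <- split_train_test(rbind(d1, tiny)), "excluded")
  expect_false(3L %in% sp2$train$session)
})

test_that("cross-validation folds partition the training span", {
  idx <- facestates:::cv_fold_indices(103, 5)
  expect_identical(sort(unlist(idx)), 1:103)
  for (f in idx) expect_identical(f, min(f):max(f))  # contiguous blocks
  expect_identical(length(idx), 5L)
})

test_that("state-number selection takes the largest finite difference", {
  curve <- c(`1` = 0.1, `2` = 0.5, `3` = 0.7, `4` = 0.75)
  expect_identical(select_n_states(curve), 2L)
  # flat curve: first difference wins by the smaller-S tie rule
  expect_identical(select_n_states(c(`1` = 0.4, `2` = 0.4, `3` = 0.4)), 2L)
  expect_error(select_n_states(c(`1` = 0.2)), "2 points")
})

test_that("noiseless single-state data cross-validate at R^2 of 1", {
  set.seed(2)
  X <- matrix(rnorm(300 * 2), 300)
  data <- data.frame(session = 1, X, rt = as.vector(X %*% c(1, -1)) + 2,
                     is_padding = FALSE, trial = 1:300)
  names(data)[2:3] <- paste0("x_", 1:2)
  cv <- time_blocked_cv(data, 1, k = 3, reps = 1, seed = 3,
                        n_iter = 5, n_restarts = 1)
  expect_equal(cv$results$r2, rep(1, 3), tolerance = 1e-6)
})

test_that("shuffling the emissions sends the CV score below zero", {
  fx <- make_recovery_fixture(600, n_states = 3, seed = 11)
  cv <- time_blocked_cv(fx$sim$data, 3, alpha = 1, beta = 20, k = 3,
                        reps = 1, seed = 5, n_iter = 15, n_restarts = 1)
  # real pairing predicts well ...
  expect_gt(mean(cv$results$r2), 0.5)
  # ... but scoring the same held-out predictions against uniformly
  # shuffled emissions collapses below zero
  set.seed(4)
  shuffled <- vapply(seq_len(200), function(i) {
    r_squared_test(sample(cv$predictions$observed),
                   cv$predictions$predicted)
  }, numeric(1))
  expect_lte(mean(shuffled), 0)
})

test_that("the CV curve saturates at the generating state count", {
  fx <- make_recovery_fixture(1200, n_states = 3, n_features = 3,
                              noise_sd = 0.1, seed = 21)
  curve <- vapply(1:4, function(S) {
    cv <- time_blocked_cv(fx$sim$data, S, alpha = 1, beta = 20, k = 3,
                          reps = 1, seed = 22, n_iter = 25,
                          n_restarts = 2)
    cv$max_r2
  }, numeric(1))
  names(curve) <- 1:4
  diffs <- diff(curve)
  # performance still improves up to the true state count ...
  expect_true(all(diffs[1:2] > 0.02))
  # ... and saturates beyond it
  expect_lt(abs(diffs[3]), 0.02)
})

test_that("hyperparameter search stays in range and is reproducible", {
  # a cheap analytic objective isolates the optimiser behaviour
  backend_obj <- function(alpha, beta) {
    -((alpha - 30)^2 / 100 + (beta - 60)^2 / 100)
  }
  h1 <- random_search_backend(backend_obj, c(0, 100), c(0, 100), 30,
                              seed = 7)
  h2 <- random_search_backend(backend_obj, c(0, 100), c(0, 100), 30,
                              seed = 7)
  expect_identical(h1, h2)  # bitwise-identical history
  expect_true(all(h1$alpha >= 0 & h1$alpha <= 100))
  expect_true(all(h1$beta >= 0 & h1$beta <= 100))
  best <- h1[which.max(h1$value), ]
  expect_identical(best$value, max(h1$value))
  # refinement moves the incumbent towards the optimum
  expect_lt(abs(best$alpha - 30) + abs(best$beta - 60), 60)
})

test_that("hyperparameter search over CV returns its history optimum", {
  fx <- make_recovery_fixture(300, n_states = 2, n_features = 2,
                              seed = 31)
  res <- hyperparam_search(fx$sim$data, 2, n_trials = 4, seed = 8,
                           k = 2, reps = 1, n_iter = 8, n_restarts = 1)
  expect_identical(res$value, max(res$history$value))
  expect_true(res$alpha >= 0 && res$alpha <= 100)
  expect_identical(nrow(res$history), 4L)
})

test_that("the shuffle surrogate sits below zero and below the model", {
  fx <- make_recovery_fixture(500, n_states = 3, seed = 41)
  fit <- fit_em(fx$sim$data, 3, alpha = 1, beta = 20, n_iter = 25,
                n_restarts = 2, seed = 42)
  sur <- surrogate_performance(fit, fx$sim$data, n_shuffles = 200,
                               percentile = 99, seed = 43)
  expect_lt(median(sur$r2), 0)
  # percentile monotonicity
  sur90 <- quantile(sur$r2, 0.90)
  expect_lte(sur90, sur$threshold)
  # the real model's performance clears the chance floor
  pred <- mslr_predict(fit$params, feature_matrix(fx$sim$data),
                       fx$sim$data$rt)
  expect_gt(r_squared_test(fx$sim$data$rt, pred$predicted),
            sur$threshold)
})

test_that("an emission-independent model stays below its surrogate", {
  # y independent of X: the fitted model's true R^2 should fall below the
  # 99th-percentile threshold in most seeded replicates
  hits <- 0L
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    set.seed(50 + i)
    X <- matrix(rnorm(200 * 2), 200)
    data <- data.frame(session = 1, X, rt = rnorm(200),
                       is_padding = FALSE, trial = 1:200)
    names(data)[2:3] <- paste0("x_", 1:2)
    half <- 1:100
    fit <- fit_em(data[half, ], 1, n_iter = 5, n_restarts = 1,
                  seed = 51 + i)
    test_rows <- data[101:200, ]
    pred <- mslr_predict(fit$params, feature_matrix(test_rows),
                         test_rows$rt)
    r2 <- r_squared_test(test_rows$rt, pred$predicted)
    sur <- surrogate_performance(fit, test_rows, n_shuffles = 100,
                                 percentile = 99, seed = 52 + i)
    if (r2 < sur$threshold) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("state matching maximises assignment weight and is stable", {
  set.seed(61)
  for (i in 1:10) {
    score <- matrix(runif(16), 4)
    got <- facestates:::match_states(score)
    perms <- facestates:::permutations_of(1:4, 4)
    vals <- apply(perms, 1, function(p) sum(score[cbind(1:4, p)]))
    expect_equal(sum(score[cbind(1:4, got)]), max(vals), tolerance = 1e-12)
  }
})

test_that("sequence correlation is invariant to relabelling the truth", {
  set.seed(62)
  z_true <- sample(1:3, 400, replace = TRUE)
  z_inf <- z_true
  flip <- runif(400) < 0.1
  z_inf[flip] <- sample(1:3, sum(flip), replace = TRUE)
  base <- state_sequence_correlation(z_true, z_inf)
  perm <- c(2, 3, 1)
  relabelled <- state_sequence_correlation(perm[z_true], z_inf)
  expect_equal(sort(base$diagonal), sort(relabelled$diagonal),
               tolerance = 1e-12)
})
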