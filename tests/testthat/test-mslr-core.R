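# MSLR core: emission densities, forward-backward smoothing against
# exhaustive enumeration, MAP M-step, EM fitting, prediction, session
# concatenation.

rand_params <- function(S, M, seed, alpha = 1, beta = 2) {
  with_seed_ <- function(s, e) {
    set.seed(s)
    e
  }
  set.seed(seed)
  P <- make_sticky_transition_matrix(S, alpha, beta)
  mslr_params(P, matrix(rnorm(S * M), S, M), rnorm(S),
              runif(S, 0.5, 2), alpha = alpha, beta = beta)
}

test_that("emission log-densities match a direct computation", {
  # zero residual at unit variance: the standard normal at its mode
  p <- mslr_params(matrix(1), matrix(1, 1, 1), 0, 1)
  ll <- emission_loglik(p, matrix(2), y = 2)
  expect_equal(ll[1, 1], -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:10) {
    params <- rand_params(3, 4, seed = i)
    X <- matrix(rnorm(20 * 4), 20)
    y <- rnorm(20)
    ll <- emission_loglik(params, X, y)
    for (s in 1:3) {
      mu <- X %*% params$weights[s, ] + params$biases[s]
      expect_equal(ll[, s],
                   direct_normal_logdensity(y, as.vector(mu),
                                            params$emission_vars[s]),
                   tolerance = 1e-12)
    }
  }
  # identical state parameters produce identical columns
  p_dup <- mslr_params(matrix(0.5, 2, 2), matrix(1, 2, 3), c(2, 2),
                       c(1, 1))
  ll_dup <- emission_loglik(p_dup, matrix(rnorm(15), 5), rnorm(5))
  expect_equal(ll_dup[, 1], ll_dup[, 2])
})

test_that("smoothing equals exhaustive path enumeration", {
  set.seed(2)
  for (i in 1:12) {
    S <- sample(2:3, 1)
    T_ <- sample(3:6, 1)
    params <- rand_params(S, 2, seed = 100 + i)
    ll <- matrix(rnorm(T_ * S), T_, S)
    reset <- c(TRUE, runif(T_ - 1) < 0.25)
    post <- forward_backward(params, ll, reset_mask = reset)
    oracle <- enumerate_smoother(params$transitions, rep(1 / S, S), ll,
                                 reset)
    expect_equal(post$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(post$smoothed, oracle$gamma, tolerance = 1e-10)
  }
})

test_that("smoothing degenerates correctly in symmetric cases", {
  # single state: posterior is 1, log-likelihood is the plain sum
  p1 <- mslr_params(matrix(1), matrix(1, 1, 2), 0, 1)
  ll <- matrix(rnorm(8), 8, 1)
  post <- forward_backward(p1, ll)
  expect_equal(post$smoothed, matrix(1, 8, 1))
  expect_equal(post$loglik, sum(ll))
  # uniform dynamics and identical emissions: posterior is uniform
  p3 <- mslr_params(matrix(1 / 3, 3, 3), matrix(0, 3, 2), rep(0, 3),
                    rep(1, 3))
  ll3 <- matrix(rep(rnorm(6), 3), 6, 3)
  post3 <- forward_backward(p3, ll3)
  expect_equal(post3$smoothed, matrix(1 / 3, 6, 3), tolerance = 1e-12)
})

test_that("the M-step solves the weighted regression and MAP rows", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60)
  y <- rnorm(60)
  z <- sample(1:2, 60, replace = TRUE)
  gamma <- one_hot <- matrix(0, 60, 2)
  gamma[cbind(1:60, z)] <- 1
  post <- structure(list(smoothed = gamma, xi_sum = matrix(c(10, 5, 3, 20), 2)),
                    class = "mslr_posterior")
  up <- m_step(X, y, post, alpha = 1, beta = 1)
  # hard assignments: per-state ordinary least squares (normal equations)
  for (s in 1:2) {
    sel <- z == s
    D <- cbind(X[sel, ], 1)
    beta_hat <- solve(t(D) %*% D, t(D) %*% y[sel])
    expect_equal(up$weights[s, ], beta_hat[1:3], tolerance = 1e-8)
    expect_equal(up$biases[s], beta_hat[4], tolerance = 1e-8)
  }
  # flat prior: transition rows are plain count normalisation
  expect_equal(up$transitions,
               post$xi_sum / rowSums(post$xi_sum), tolerance = 1e-12)
  # dominant stickiness drives rows to the identity
  up_sticky <- m_step(X, y, post, alpha = 1, beta = 1e9)
  expect_equal(up_sticky$transitions, diag(2), tolerance = 1e-6)
})

test_that("EM objective is monotone and the flat-prior trace as well", {
  fx <- make_recovery_fixture(300, seed = 31)
  # flat prior: MAP EM coincides with maximum likelihood; the raw
  # log-likelihood trace must be non-decreasing
  for (s in 1:3) {
    fit <- fit_em(fx$sim$data, 2, alpha = 1, beta = 1, n_iter = 15,
                  n_restarts = 2, seed = s)
    for (r in seq_len(ncol(fit$trace))) {
      expect_true(all(diff(fit$trace[, r]) > -1e-8))
    }
  }
  # sticky prior: the penalized objective is the monotone quantity
  for (s in 1:3) {
    fit <- fit_em(fx$sim$data, 2, alpha = 2, beta = 10, n_iter = 15,
                  n_restarts = 2, seed = s)
    for (r in seq_len(ncol(fit$objective_trace))) {
      expect_true(all(diff(fit$objective_trace[, r]) > -1e-8))
    }
  }
})

test_that("a single-state fit equals global least squares", {
  set.seed(4)
  X <- matrix(rnorm(200 * 3), 200)
  y <- X %*% c(1, -2, 0.5) + 0.3 + rnorm(200, sd = 0.4)
  data <- data.frame(session = 1, X, rt = as.vector(y),
                     is_padding = FALSE)
  names(data)[2:4] <- paste0("x_", 1:3)
  fit <- fit_em(data, 1, n_iter = 5, n_restarts = 1, seed = 1)
  ls <- lm(rt ~ x_1 + x_2 + x_3, data)
  expect_equal(fit$params$weights[1, ], unname(coef(ls)[2:4]),
               tolerance = 1e-6)
  expect_equal(fit$params$biases[1], unname(coef(ls)[1]), tolerance = 1e-6)
})

test_that("EM recovers well-separated state weights and sequences", {
  fx <- make_recovery_fixture(3000, n_states = 3, n_features = 4,
                              noise_sd = 0.1, seed = 41)
  fit <- fit_em(fx$sim$data, 3, alpha = 1, beta = 20, n_iter = 50,
                n_restarts = 5, seed = 42)
  sc <- state_sequence_correlation(fx$sim$truth$state_sequence,
                                   fit$posterior$argmax_state)
  perm <- sc$assignment
  for (s in 1:3) {
    expect_gte(cor(fx$params$weights[s, ], fit$params$weights[perm[s], ]),
               0.95)
  }
  # argmax states match the truth on at least 90% of trials
  expect_gte(mean(perm[fx$sim$truth$state_sequence] ==
                    fit$posterior$argmax_state), 0.9)
})

test_that("state relabelling leaves label-free statistics unchanged", {
  fx <- make_recovery_fixture(200, n_states = 3, seed = 51)
  perm <- c(3, 1, 2)
  p0 <- fx$params
  p_perm <- mslr_params(p0$transitions[perm, perm],
                        p0$weights[perm, , drop = FALSE],
                        p0$biases[perm], p0$emission_vars[perm],
                        alpha = p0$alpha, beta = p0$beta)
  X <- feature_matrix(fx$sim$data)
  y <- fx$sim$data$rt
  post0 <- forward_backward(p0, emission_loglik(p0, X, y))
  post1 <- forward_backward(p_perm, emission_loglik(p_perm, X, y))
  expect_equal(post0$loglik, post1$loglik, tolerance = 1e-10)
  pred0 <- mslr_predict(p0, X, y)
  pred1 <- mslr_predict(p_perm, X, y)
  expect_equal(pred0$predicted, pred1$predicted, tolerance = 1e-10)
  dw0 <- dwell_times(post0$argmax_state)
  dw1 <- dwell_times(post1$argmax_state)
  expect_identical(sort(unlist(dw0, use.names = FALSE)),
                   sort(unlist(dw1, use.names = FALSE)))
})

test_that("prediction mixes the per-state regressions by posterior", {
  fx <- make_recovery_fixture(100, n_states = 2, seed = 61)
  X <- feature_matrix(fx$sim$data)
  # one-hot posterior: prediction is that state's regression exactly
  p <- fx$params
  mu <- sweep(X %*% t(p$weights), 2, p$biases, `+`)
  post <- forward_backward(p, emission_loglik(p, X, fx$sim$data$rt))
  manual <- rowSums(post$smoothed * mu)
  expect_equal(mslr_predict(p, X, fx$sim$data$rt)$predicted, manual,
               tolerance = 1e-12)
  # identical states: prediction no longer depends on the posterior
  p_same <- mslr_params(matrix(0.5, 2, 2),
                        rbind(p$weights[1, ], p$weights[1, ]),
                        rep(p$biases[1], 2), rep(0.5, 2))
  pr <- mslr_predict(p_same, X, fx$sim$data$rt)
  expect_equal(pr$predicted,
               as.vector(X %*% p$weights[1, ] + p$biases[1]),
               tolerance = 1e-12)
})

test_that("noiseless synthetic data are predicted with R^2 of 1", {
  fx <- make_recovery_fixture(400, n_states = 3, noise_sd = 1e-8,
                              seed = 71)
  fit <- fit_em(fx$sim$data, 3, alpha = 1, beta = 20, n_iter = 30,
                n_restarts = 3, seed = 72)
  pred <- mslr_predict(fit$params, feature_matrix(fx$sim$data),
                       fx$sim$data$rt)
  expect_equal(r_squared_test(fx$sim$data$rt, pred$predicted), 1,
               tolerance = 1e-6)
})

test_that("session concatenation pads with flagged zero trials", {
  fx <- make_recovery_fixture(100, seed = 81)
  s1 <- fx$sim$data
  s2 <- fx$sim$data
  s2$session <- 2L
  stacked <- concatenate_sessions(list(s1, s2))
  expect_identical(nrow(stacked), 250L)
  expect_identical(sum(stacked$is_padding), 50L)
  expect_true(all(feature_matrix(stacked)[stacked$is_padding, ] == 0))
  expect_true(all(stacked$rt[stacked$is_padding] == 0))
  # single session: unchanged, nothing flagged
  alone <- concatenate_sessions(list(s1))
  expect_identical(nrow(alone), 100L)
  expect_identical(sum(alone$is_padding), 0L)
  # k sessions of n trials: k*n + (k-1)*pad rows
  three <- concatenate_sessions(list(s1, s1, s1), pad = 10)
  expect_identical(nrow(three), 3L * 100L + 2L * 10L)
})

test_that("padding and explicit resets agree on non-padding trials", {
  fx1 <- make_recovery_fixture(150, seed = 91)
  fx2 <- make_recovery_fixture(150, seed = 92)
  s1 <- fx1$sim$data
  s2 <- fx2$sim$data
  s2$session <- 2L
  # same ground truth parameters drive both sessions
  stacked <- concatenate_sessions(list(s1, s2))
  fit <- fit_em(stacked, 3, alpha = 1, beta = 20, n_iter = 40,
                n_restarts = 3, seed = 93, session_reset = "padding")
  # evaluate the same fitted parameters under both reset conventions
  ch_pad <- stacked
  keep <- !stacked$is_padding
  pred_pad <- mslr_predict(fit$params, feature_matrix(ch_pad), ch_pad$rt)
  post_pad <- pred_pad$posterior$smoothed[keep, ]
  plain <- stacked[keep, , drop = FALSE]
  reset <- c(TRUE, plain$session[-1] != plain$session[-nrow(plain)])
  pred_reset <- mslr_predict(fit$params, feature_matrix(plain), plain$rt,
                             reset_mask = reset)
  expect_equal(post_pad, pred_reset$posterior$smoothed, tolerance = 0.02)
})
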