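# Markov-switching linear regression: emission model, forward-backward
# smoothing, EM with MAP transition updates under a sticky Dirichlet
# prior, and prediction.

#' Per-trial, per-state log emission densities
#'
#' Entry (t, s) is the log Gaussian density of the observed emission `y[t]`
#' under state s: mean `W_s x_t + b_s`, variance `emission_vars[s]`.
#'
#' @param params an [mslr_params] object.
#' @param X predictor matrix (T x M).
#' @param y emission vector (reaction times), length T.
#' @return T x S matrix of log densities.
#' @export
emission_loglik <- function(params, X, y) {
  stopifnot(inherits(params, "mslr_params"))
  X <- as.matrix(X)
  if (ncol(X) != params$n_features) {
    stop_invalid("X has %d columns, params expect %d", ncol(X),
                 params$n_features)
  }
  if (length(y) != nrow(X)) stop_invalid("length(y) must equal nrow(X)")
  if (any(params$emission_vars <= 0)) {
    stop_invalid("emission variances must be > 0")
  }
  mu <- X %*% t(params$weights)  # T x S
  mu <- sweep(mu, 2L, params$biases, `+`)
  sds <- sqrt(params$emission_vars)
  ll <- dnorm(y, mean = mu, sd = rep(sds, each = nrow(mu)), log = TRUE)
  matrix(ll, nrow(mu), params$n_states)
}

#' Forward-backward smoothing over the latent state chain
#'
#' Computes the smoothed posterior state probabilities p(z_t = s | all
#' data), the expected pairwise transition counts, and the exact marginal
#' log-likelihood, using the standard scaled forward-backward recursions.
#' At positions flagged in `reset_mask` (session boundaries) the state
#' distribution is re-initialised from `init` instead of propagating
#' through the transition matrix; position 1 is always a reset.
#'
#' @param params an [mslr_params] object.
#' @param loglik T x S log emission density matrix (see [emission_loglik]);
#'   all entries must be finite.
#' @param reset_mask logical vector of length T, or NULL for a single
#'   uninterrupted chain.
#' @param init initial/reset state distribution; default uniform.
#' @param store_xi keep the full (T-1) x S x S pairwise transition
#'   posterior array (memory-heavy for long chains).
#' @return an object of class `mslr_posterior`: list with `smoothed`
#'   (T x S), `xi_sum` (S x S expected transition counts), `loglik`
#'   (marginal log-likelihood, nats), `argmax_state` (length T), and
#'   optionally `xi`.
#' @export
forward_backward <- function(params, loglik, reset_mask = NULL,
                             init = NULL, store_xi = FALSE) {
  stopifnot(inherits(params, "mslr_params"))
  loglik <- as.matrix(loglik)
  S <- params$n_states
  if (ncol(loglik) != S) stop_invalid("loglik must have S = %d columns", S)
  if (!all(is.finite(loglik))) stop_invalid("loglik entries must be finite")
  T_ <- nrow(loglik)
  if (is.null(reset_mask)) reset_mask <- rep(FALSE, T_)
  if (length(reset_mask) != T_) {
    stop_invalid("reset_mask must have length %d", T_)
  }
  if (is.null(init)) init <- rep(1 / S, S)
  res <- fb_smooth_cpp(loglik, params$transitions, init,
                       as.integer(reset_mask), isTRUE(store_xi))
  out <- list(smoothed = res$gamma, xi_sum = res$xi_sum,
              loglik = res$loglik,
              argmax_state = max.col(res$gamma, ties.method = "first"))
  if (isTRUE(store_xi)) out$xi <- res$xi
  structure(out, class = "mslr_posterior")
}

#' M-step: MAP parameter update from smoothed posteriors
#'
#' Per state, the weights and bias solve the responsibility-weighted
#' least-squares problem and the emission variance is the weighted mean
#' squared residual (floored at `var_floor`). Transition row i is
#' proportional to the expected transition counts plus `(alpha - 1)` on
#' every entry and `(beta - 1)` on the diagonal, clipped at zero before
#' normalisation (the MAP update under the sticky Dirichlet prior). A
#' state whose total responsibility falls below 1e-8 is re-initialised
#' from a fresh standard-normal draw (with unit variance) rather than
#' deleted, preserving S.
#'
#' @param X,y data (T x M matrix, length-T vector).
#' @param posterior an `mslr_posterior` from [forward_backward].
#' @param alpha,beta sticky Dirichlet pseudo-counts.
#' @param var_floor lower bound on emission variances.
#' @return an [mslr_params] object.
#' @export
m_step <- function(X, y, posterior, alpha = 1, beta = 1, var_floor = 1e-6) {
  X <- as.matrix(X)
  gamma <- posterior$smoothed
  S <- ncol(gamma)
  M <- ncol(X)
  W <- matrix(0, S, M)
  b <- numeric(S)
  vars <- numeric(S)
  design <- cbind(X, intercept = 1)
  for (s in seq_len(S)) {
    w <- gamma[, s]
    tot <- sum(w)
    if (tot < 1e-8) {
      message(sprintf("state %d received negligible responsibility; re-seeded", s))
      W[s, ] <- rnorm(M)
      b[s] <- rnorm(1)
      vars[s] <- 1
      next
    }
    fit <- lm.wfit(design, y, w)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    W[s, ] <- cf[seq_len(M)]
    b[s] <- cf[M + 1]
    resid <- y - (X %*% cf[seq_len(M)] + cf[M + 1])
    vars[s] <- max(sum(w * resid^2) / tot, var_floor)
  }
  A <- posterior$xi_sum + (alpha - 1)
  diag(A) <- diag(A) + (beta - 1)
  A[A < 0] <- 0
  rs <- rowSums(A)
  P <- matrix(1 / S, S, S)
  ok <- rs > 0
  P[ok, ] <- A[ok, , drop = FALSE] / rs[ok]
  mslr_params(P, W, b, vars, alpha = alpha, beta = beta)
}

#' Concatenate sessions with zero-padded forced transitions
#'
#' Sessions are stacked in order with `pad` all-zero trials (predictors and
#' emissions 0) flagged as padding inserted between consecutive sessions,
#' so the state probabilities are forced to reset between sessions.
#' Padding trials are excluded from all downstream performance metrics and
#' state statistics.
#'
#' @param sessions a list of trial data frames (each with `x_*` feature
#'   columns and an `rt` column), or a single data frame with a `session`
#'   column that is split in order of appearance.
#' @param pad number of zero trials inserted between sessions.
#' @return a single trial data frame with an `is_padding` column.
#' @export
concatenate_sessions <- function(sessions, pad = 50) {
  if (is.data.frame(sessions)) {
    sessions <- split(sessions, factor(sessions$session,
                                       levels = unique(sessions$session)))
  }
  stopifnot(length(sessions) >= 1)
  template <- sessions[[1]]
  if (!"is_padding" %in% names(template)) {
    sessions <- lapply(sessions, function(s) {
      s$is_padding <- FALSE
      s
    })
    template <- sessions[[1]]
  }
  pad_block <- template[rep(1L, pad), , drop = FALSE]
  pad_block[feature_cols(template)] <- 0
  pad_block$rt <- 0
  pad_block$is_padding <- TRUE
  if ("state_true" %in% names(pad_block)) pad_block$state_true <- NA_integer_
  if ("outcome" %in% names(pad_block)) pad_block$outcome <- NA_character_
  pad_block$session <- NA
  out <- sessions[[1]]
  if (length(sessions) > 1) {
    for (i in 2:length(sessions)) {
      out <- rbind(out, pad_block, sessions[[i]])
    }
  }
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out
}

# Session-reset bookkeeping: under "padding" mode the stacked data are one
# literal chain (reset only at t = 1); under "reset" mode padding rows are
# dropped and the chain re-initialises at each session start.
prepare_chain <- function(data, session_reset = c("padding", "reset")) {
  session_reset <- match.arg(session_reset)
  if (is.null(data$is_padding)) data$is_padding <- FALSE
  if (session_reset == "reset") {
    keep <- !data$is_padding
    data <- data[keep, , drop = FALSE]
    sess <- data$session
    reset <- c(TRUE, sess[-1] != sess[-length(sess)] |
                 (is.na(sess[-1]) != is.na(sess[-length(sess)])))
  } else {
    reset <- rep(FALSE, nrow(data))
    reset[1] <- TRUE
  }
  list(data = data, X = feature_matrix(data), y = data$rt, reset = reset)
}

# Dirichlet MAP exponent used both in the M-step and in the penalized
# objective that MAP-EM increases monotonically.
transition_log_prior <- function(params) {
  a <- params$alpha - 1
  bdiag <- params$beta - 1
  lp <- log(pmax(params$transitions, .Machine$double.xmin))
  a * sum(lp) + bdiag * sum(diag(lp))
}

#' Fit an MSLR by expectation-maximisation with restarts
#'
#' Each restart initialises weights and biases from a standard normal,
#' emission variances at 1 (the scalar analogue of an identity
#' covariance), and transitions at the sticky-prior mean; EM then
#' alternates forward-backward smoothing with MAP updates for `n_iter`
#' iterations. The restart with the highest final marginal log-likelihood
#' is returned. Results are deterministic given `seed`.
#'
#' @param data a trial data frame (see [concatenate_sessions]) with `x_*`
#'   feature columns and `rt`.
#' @param n_states number of latent states S.
#' @param alpha,beta sticky Dirichlet transition pseudo-counts.
#' @param n_iter EM iterations per restart.
#' @param n_restarts independent initialisations.
#' @param seed integer seed.
#' @param var_floor emission variance floor.
#' @param session_reset `"padding"` treats the stacked data as one literal
#'   chain (zero-padding rows force the resets); `"reset"` drops padding
#'   rows and re-initialises the chain at every session boundary.
#' @return an object of class `mslr_fit`: list with `params`, `loglik`
#'   (final marginal log-likelihood of the best restart), `trace` (matrix,
#'   iteration x restart, marginal log-likelihood before each update),
#'   `objective_trace` (same shape; log-likelihood plus transition
#'   log-prior, the quantity MAP-EM increases), `posterior` (final
#'   smoothed posteriors of the best restart, non-padding rows), `seed`,
#'   and the data/bookkeeping needed for prediction.
#' @export
fit_em <- function(data, n_states, alpha = 1, beta = 1, n_iter = 50,
                   n_restarts = 10, seed = NULL, var_floor = 1e-6,
                   session_reset = c("padding", "reset")) {
  session_reset <- match.arg(session_reset)
  if (nrow(data) < 1) stop_invalid("data must be nonempty")
  if (n_states < 1) stop_invalid("n_states must be >= 1")
  chain <- prepare_chain(data, session_reset)
  X <- chain$X
  y <- chain$y
  M <- ncol(X)
  S <- n_states
  prior_mean <- {
    A <- matrix(alpha, S, S)
    diag(A) <- diag(A) + beta
    if (all(rowSums(A) == 0)) diag(S) * 0 + 1 / S else A / rowSums(A)
  }
  trace <- matrix(NA_real_, n_iter + 1, n_restarts)
  obj_trace <- matrix(NA_real_, n_iter + 1, n_restarts)
  best <- NULL
  best_ll <- -Inf
  for (r in seq_len(n_restarts)) {
    ok <- TRUE
    with_seed(child_seed(seed, r), {
      params <- mslr_params(prior_mean,
                            matrix(rnorm(S * M), S, M), rnorm(S),
                            rep(1, S), alpha = alpha, beta = beta)
      post <- NULL
      for (it in seq_len(n_iter)) {
        ll <- emission_loglik(params, X, y)
        post <- forward_backward(params, ll, chain$reset)
        if (!is.finite(post$loglik)) {
          message(sprintf("restart %d: non-finite likelihood, discarded", r))
          ok <- FALSE
          break
        }
        trace[it, r] <- post$loglik
        obj_trace[it, r] <- post$loglik + transition_log_prior(params)
        params <- m_step(X, y, post, alpha = alpha, beta = beta,
                         var_floor = var_floor)
      }
      if (ok) {
        ll <- emission_loglik(params, X, y)
        post <- forward_backward(params, ll, chain$reset)
        trace[n_iter + 1, r] <- post$loglik
        obj_trace[n_iter + 1, r] <- post$loglik + transition_log_prior(params)
        if (is.finite(post$loglik) && post$loglik > best_ll) {
          best_ll <- post$loglik
          best <- list(params = params, posterior = post, restart = r)
        }
      }
    })
  }
  if (is.null(best)) stop_invalid("all EM restarts failed")
  structure(
    list(params = best$params, loglik = best_ll, trace = trace,
         objective_trace = obj_trace, restart = best$restart,
         posterior = best$posterior, seed = seed,
         session_reset = session_reset, n_iter = n_iter,
         n_restarts = n_restarts),
    class = "mslr_fit")
}

#' @export
print.mslr_fit <- function(x, ...) {
  cat(sprintf(
    "MSLR fit: %d states, %d features; logLik %.2f (best of %d restarts)\n",
    x$params$n_states, x$params$n_features, x$loglik, x$n_restarts))
  invisible(x)
}

#' Predict reaction times and smoothed states
#'
#' Smoothed posteriors are computed with the supplied emissions
#' (`y_for_inference`); the predicted reaction time is the
#' posterior-weighted mixture of the per-state linear predictions, and
#' each trial is assigned to its most probable state.
#'
#' @param object an `mslr_fit` or [mslr_params] object.
#' @param X predictor matrix.
#' @param y_for_inference emission vector used for state inference.
#' @param reset_mask optional logical reset positions (see
#'   [forward_backward]).
#' @param ... unused.
#' @return list with `predicted` (length T) and `posterior`
#'   (`mslr_posterior`).
#' @export
predict.mslr_fit <- function(object, X, y_for_inference,
                             reset_mask = NULL, ...) {
  mslr_predict(object$params, X, y_for_inference, reset_mask)
}

#' @rdname predict.mslr_fit
#' @param params an [mslr_params] object.
#' @export
mslr_predict <- function(params, X, y_for_inference, reset_mask = NULL) {
  X <- as.matrix(X)
  ll <- emission_loglik(params, X, y_for_inference)
  post <- forward_backward(params, ll, reset_mask)
  mu <- sweep(X %*% t(params$weights), 2L, params$biases, `+`)
  list(predicted = rowSums(post$smoothed * mu), posterior = post)
}
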