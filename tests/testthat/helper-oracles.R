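# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (enumeration, direct
# formula, explicit pair counting) kept separate from the package's code
# paths.

# Exhaustive-path forward-backward: enumerate all S^T state paths and sum
# their joint densities. `reset` marks positions where the chain restarts
# from `init` (position 1 always does).
enumerate_smoother <- function(trans, init, loglik, reset = NULL) {
  T_ <- nrow(loglik)
  S <- ncol(loglik)
  if (is.null(reset)) reset <- rep(FALSE, T_)
  reset[1] <- TRUE
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  logp <- apply(paths, 1L, function(z) {
    lp <- 0
    for (t in seq_len(T_)) {
      lp <- lp + if (reset[t]) log(init[z[t]]) else
        log(trans[z[t - 1], z[t]])
      lp <- lp + loglik[t, z[t]]
    }
    lp
  })
  m <- max(logp)
  tot <- m + log(sum(exp(logp - m)))
  w <- exp(logp - tot)
  gamma <- matrix(0, T_, S)
  for (t in seq_len(T_)) {
    for (s in seq_len(S)) gamma[t, s] <- sum(w[paths[, t] == s])
  }
  list(loglik = tot, gamma = gamma)
}

# Vargha-Delaney A by explicit pair counting (ties worth 1/2).
brute_force_A <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(b))
}

# Peak prominence by explicit definition: walk out from the peak until a
# strictly higher value (or the edge); bases are the minima on each walk.
brute_force_prominence <- function(x, peak) {
  x[is.na(x)] <- -Inf
  left <- x[seq_len(peak - 1)]
  higher_l <- which(left > x[peak])
  lo_l <- if (length(higher_l)) max(higher_l) + 1L else 1L
  base_l <- min(x[lo_l:peak])
  right <- x[(peak + 1):length(x)]
  higher_r <- which(right > x[peak])
  hi_r <- if (length(higher_r)) peak + min(higher_r) - 1L else length(x)
  base_r <- min(x[peak:hi_r])
  x[peak] - max(base_l, base_r)
}

# Direct log-density of a scalar normal, written out.
direct_normal_logdensity <- function(y, mu, var) {
  -0.5 * log(2 * pi * var) - (y - mu)^2 / (2 * var)
}

# Jensen-Shannon distance by the textbook formula, base-2 logs.
direct_js_distance <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    s <- 0
    for (i in seq_along(a)) {
      if (a[i] > 0) s <- s + a[i] * log2(a[i] / m[i])
    }
    s
  }
  sqrt(0.5 * term(p) + 0.5 * term(q))
}

# Plain re-implementations of small conveniences so tests do not reach
# into the package internals.
feature_matrix <- function(data) {
  as.matrix(data[, grep("^x_[0-9]+$", names(data)), drop = FALSE])
}

r_squared_test <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

# Small well-separated multi-state dataset for recovery-style checks.
make_recovery_fixture <- function(n_trials, n_states = 3, n_features = 4,
                                  noise_sd = 0.1, seed = 1) {
  params <- make_ground_truth_params(
    n_states, n_features, alpha = 1, beta = 20,
    emission_noise_sd = noise_sd, seed = seed)
  X <- generate_facial_inputs(n_trials, n_features, ar_coef = 0.3,
                              seed = seed + 1)
  sim <- sample_mslr_dataset(params, X, seed = seed + 2)
  list(params = params, sim = sim)
}
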