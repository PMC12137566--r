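# Synthetic-data generator: every input the pipeline consumes, with the
# statistical structure the analysis assumes, so all stages are testable
# with known ground truth.

#' Draw a sticky row-Dirichlet transition matrix
#'
#' Each row is drawn from a Dirichlet distribution with concentration
#' `alpha` on every entry plus `beta` added to the diagonal entry, so large
#' `beta` biases self-transitions (sticky states) and large `alpha` pushes
#' rows towards uniform.
#'
#' @param n_states number of latent states (S >= 1).
#' @param alpha concentration pseudo-count, >= 0.
#' @param beta diagonal stickiness pseudo-count, >= 0. `alpha` and `beta`
#'   must not both be 0 (the prior would be improper).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return S x S row-stochastic matrix.
#' @export
make_sticky_transition_matrix <- function(n_states, alpha, beta, seed = NULL) {
  if (n_states < 1) stop_invalid("n_states must be >= 1")
  if (alpha < 0 || beta < 0) stop_invalid("alpha and beta must be >= 0")
  if (alpha == 0 && beta == 0) {
    stop_invalid("alpha and beta must not both be 0 (improper prior)")
  }
  with_seed(seed, {
    P <- matrix(0, n_states, n_states)
    for (i in seq_len(n_states)) {
      conc <- rep(alpha, n_states)
      conc[i] <- conc[i] + beta
      g <- rgamma(n_states, shape = conc)
      # a gamma draw with tiny shape can underflow to all-zero rows
      if (sum(g) == 0) g[which.max(conc)] <- 1
      P[i, ] <- g / sum(g)
    }
    P
  })
}

#' Generate autocorrelated synthetic facial-feature predictors
#'
#' Each feature column is a stationary first-order autoregressive series
#' with unit marginal variance, emulating the slow trial-to-trial drift of
#' pre-stimulus facial features.
#'
#' @param n_trials number of trials (rows).
#' @param n_features number of feature columns (M).
#' @param ar_coef lag-1 autoregressive coefficient in [0, 1).
#' @param seed integer seed.
#' @return n_trials x M numeric matrix with columns named `x_1 ... x_M`.
#' @export
generate_facial_inputs <- function(n_trials, n_features, ar_coef = 0.3,
                                   seed = NULL) {
  if (n_trials < 1 || n_features < 1) {
    stop_invalid("n_trials and n_features must be >= 1")
  }
  if (ar_coef < 0 || ar_coef >= 1) {
    stop_invalid("ar_coef must lie in [0, 1) for a stationary series")
  }
  with_seed(seed, {
    innov_sd <- sqrt(1 - ar_coef^2)
    X <- matrix(0, n_trials, n_features)
    X[1, ] <- rnorm(n_features)
    if (n_trials > 1) {
      for (t in 2:n_trials) {
        X[t, ] <- ar_coef * X[t - 1, ] + innov_sd * rnorm(n_features)
      }
    }
    colnames(X) <- paste0("x_", seq_len(n_features))
    X
  })
}

#' Draw ground-truth MSLR parameters with separated states
#'
#' Weights are independent normals scaled by `weight_scale` and biases are
#' normals scaled by `bias_scale`. Two rejection criteria make the states
#' identifiable in recovery experiments: every pair of per-state
#' `(W_s, b_s)` vectors must be at least `min_separation` apart in
#' Euclidean distance (distinct regression rules), and every pair of
#' biases at least `min_bias_separation` apart (distinct marginal emission
#' levels, so the states remain distinguishable through their emission
#' distributions alone). The transition matrix is drawn from the sticky
#' Dirichlet prior.
#'
#' @param n_states,n_features model dimensions.
#' @param alpha,beta sticky transition prior pseudo-counts.
#' @param emission_noise_sd per-state emission (RT) standard deviation;
#'   recycled to length S.
#' @param weight_scale standard deviation of the weight draws.
#' @param bias_scale standard deviation of the bias draws, in units of
#'   `weight_scale`.
#' @param min_separation minimum pairwise distance between state parameter
#'   vectors, in units of `weight_scale`.
#' @param min_bias_separation minimum pairwise bias gap, in units of
#'   `weight_scale`.
#' @param seed integer seed.
#' @return an [mslr_params] object.
#' @export
make_ground_truth_params <- function(n_states, n_features, alpha = 1,
                                     beta = 20, emission_noise_sd = 0.3,
                                     weight_scale = 1, bias_scale = 2,
                                     min_separation = 1.5,
                                     min_bias_separation = 1.5,
                                     seed = NULL) {
  if (any(emission_noise_sd < 0)) stop_invalid("emission_noise_sd must be >= 0")
  with_seed(seed, {
    repeat {
      W <- matrix(rnorm(n_states * n_features, sd = weight_scale),
                  n_states, n_features)
      b <- rnorm(n_states, sd = bias_scale * weight_scale)
      if (n_states == 1L) break
      d <- as.matrix(stats::dist(cbind(W, b)))
      if (min(d[upper.tri(d)]) >= min_separation * weight_scale &&
          min(stats::dist(b)) >= min_bias_separation * weight_scale) break
    }
    P <- make_sticky_transition_matrix(n_states, alpha, beta)
    vars <- rep(emission_noise_sd, length.out = n_states)^2
    # mslr_params requires strictly positive variances; keep noiseless
    # ground truths representable through an epsilon floor
    vars <- pmax(vars, .Machine$double.xmin)
    mslr_params(P, W, b, vars, alpha = alpha, beta = beta)
  })
}

#' Sample a trial dataset from a ground-truth MSLR
#'
#' The state sequence starts from a uniform initial distribution and
#' evolves under the transition matrix; each trial's reaction time is drawn
#' from a Gaussian centred on the active state's linear prediction
#' `W_z x_t + b_z` with that state's emission variance.
#'
#' @param params ground-truth [mslr_params].
#' @param X predictor matrix (n_trials x M); columns are standardised
#'   (zero mean, unit variance) before emission sampling, mirroring
#'   z-scored facial inputs. Set `standardize = FALSE` to skip.
#' @param seed integer seed.
#' @param outcome_probs optional S x 3 matrix of per-state probabilities of
#'   the `hit`/`wrong`/`miss` trial outcomes; default draws outcomes
#'   uniformly, independent of state.
#' @param init_state optional fixed initial state (overrides the uniform
#'   initial draw); used to pin chains in tests.
#' @param standardize standardise predictor columns first (default TRUE).
#' @return list with `data` (a trial data frame: `session`, `trial`,
#'   `x_1 ... x_M`, `rt`, `state_true`, `outcome`, `is_padding`) and
#'   `truth` (list: `params`, `state_sequence`, `clean_emissions`).
#' @export
sample_mslr_dataset <- function(params, X, seed = NULL, outcome_probs = NULL,
                                init_state = NULL, standardize = TRUE) {
  stopifnot(inherits(params, "mslr_params"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1) stop_invalid("X must have at least one row")
  if (ncol(X) != params$n_features) {
    stop_invalid("X has %d columns but params expect %d features",
                 ncol(X), params$n_features)
  }
  S <- params$n_states
  if (standardize && n > 1) {
    X <- scale(X)
    X[!is.finite(X)] <- 0  # constant columns
  }
  if (!is.null(outcome_probs)) {
    outcome_probs <- as.matrix(outcome_probs)
    stopifnot(nrow(outcome_probs) == S, ncol(outcome_probs) == 3L)
  }
  with_seed(seed, {
    z <- integer(n)
    z[1] <- if (is.null(init_state)) sample.int(S, 1L) else as.integer(init_state)
    if (n > 1) {
      for (t in 2:n) {
        z[t] <- sample.int(S, 1L, prob = params$transitions[z[t - 1], ])
      }
    }
    clean <- rowSums(X * params$weights[z, , drop = FALSE]) + params$biases[z]
    rt <- clean + rnorm(n, sd = sqrt(params$emission_vars[z]))
    outcomes <- c("hit", "wrong", "miss")
    outcome <- if (is.null(outcome_probs)) {
      sample(outcomes, n, replace = TRUE)
    } else {
      vapply(z, function(s) sample(outcomes, 1L, prob = outcome_probs[s, ]),
             character(1))
    }
    data <- data.frame(session = 1L, trial = seq_len(n), X,
                       rt = rt, state_true = z, outcome = outcome,
                       is_padding = FALSE)
    names(data)[3:(2 + ncol(X))] <- paste0("x_", seq_len(ncol(X)))
    list(data = data,
         truth = list(params = params, state_sequence = z,
                      clean_emissions = clean))
  })
}

#' Generate a piecewise-linear virtual-movement trajectory
#'
#' Lateral position is Gaussian noise around 0 before `turn_time` and
#' around a ramp of slope `turn_rate` afterwards; forward position
#' increases monotonically at unit speed. With `turn_time = NA` the lateral
#' track is noise-only (a "miss" trajectory with no directed reaction).
#'
#' The noise is a temporally smooth Gaussian process (white noise
#' convolved with a Gaussian kernel of width `noise_tau`, rescaled to a
#' marginal standard deviation of `noise_sd`): virtual positions are
#' integrated trackball or treadmill movements, band-limited by the
#' physical dynamics, not frame-wise independent jitter.
#'
#' @param duration trajectory length, seconds.
#' @param sampling_rate samples per second (Hz).
#' @param turn_time onset of the lateral turn, seconds from trajectory
#'   start; `NA` for a turn-free track.
#' @param turn_rate lateral speed after the turn (lateral units/s).
#' @param noise_sd marginal lateral noise standard deviation.
#' @param noise_tau noise correlation time, seconds.
#' @param seed integer seed.
#' @return a `trajectory` object: list with `time`, `lateral`, `forward`,
#'   `sampling_rate`, `turn_time`.
#' @export
generate_trajectory <- function(duration, sampling_rate, turn_time = NA,
                                turn_rate = 1, noise_sd = 0.02,
                                noise_tau = 1, seed = NULL) {
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be > 0")
  if (!is.na(turn_time) && (turn_time <= 0 || turn_time >= duration)) {
    stop_invalid("turn_time must lie strictly inside (0, duration)")
  }
  n <- round(duration * sampling_rate)
  time <- (seq_len(n) - 1) / sampling_rate
  with_seed(seed, {
    lateral <- if (noise_sd > 0) {
      tau_samples <- max(1, noise_tau * sampling_rate)
      kern <- dnorm(seq(-ceiling(3 * tau_samples), ceiling(3 * tau_samples)),
                    sd = tau_samples)
      kern <- kern / sum(kern)
      pad <- length(kern)
      raw <- rnorm(n + 2 * pad)
      sm <- stats::convolve(raw, kern, type = "filter")
      sm <- sm[seq_len(n) + (length(sm) - n) %/% 2]
      sm / sd(sm) * noise_sd
    } else {
      numeric(n)
    }
    if (!is.na(turn_time)) {
      after <- time >= turn_time
      lateral[after] <- lateral[after] + turn_rate * (time[after] - turn_time)
    }
    trajectory(time, lateral, forward = time, sampling_rate = sampling_rate,
               turn_time = turn_time)
  })
}

#' Construct a trajectory object
#'
#' @param time sample times, seconds, strictly increasing and uniformly
#'   spaced.
#' @param lateral,forward lateral and forward virtual positions, same
#'   length as `time`.
#' @param sampling_rate Hz; inferred from `time` when omitted.
#' @param turn_time optional known turn time (ground truth), seconds.
#' @return a `trajectory` object.
#' @export
trajectory <- function(time, lateral, forward = NULL, sampling_rate = NULL,
                       turn_time = NA) {
  if (length(lateral) != length(time)) {
    stop_invalid("lateral and time must have the same length")
  }
  if (is.null(forward)) forward <- rep(0, length(time))
  if (length(forward) != length(time)) {
    stop_invalid("forward and time must have the same length")
  }
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
      stop_invalid("time must be strictly increasing and uniformly spaced")
    }
    if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
  }
  structure(list(time = time, lateral = lateral, forward = forward,
                 sampling_rate = sampling_rate, turn_time = turn_time),
            class = "trajectory")
}

#' Write / read a synthetic trial dataset as CSV plus JSON sidecar
#'
#' The CSV holds one row per trial (`session`, `trial`, `x_1 ... x_M`,
#' `rt`, `state_true`, `outcome`, `is_padding`); the sidecar JSON records
#' the generating parameters and seed so a run is fully reproducible.
#'
#' @param dataset a list as returned by [sample_mslr_dataset].
#' @param csv_path,json_path output paths; `json_path` defaults to the CSV
#'   path with a `.json` extension.
#' @param seed the seed used to generate the dataset (recorded only).
#' @return `write_trial_dataset` returns `csv_path` invisibly;
#'   `read_trial_dataset` returns a list with `data` and (when the sidecar
#'   is present) `truth`.
#' @export
write_trial_dataset <- function(dataset, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path),
                                seed = NULL) {
  write.csv(dataset$data, csv_path, row.names = FALSE)
  sidecar <- list(seed = seed,
                  state_sequence = dataset$truth$state_sequence)
  if (!is.null(dataset$truth$params)) {
    p <- dataset$truth$params
    sidecar$params <- list(
      n_states = p$n_states, n_features = p$n_features,
      transitions = p$transitions, weights = p$weights, biases = p$biases,
      emission_vars = p$emission_vars, alpha = p$alpha, beta = p$beta)
  }
  jsonlite::write_json(sidecar, json_path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(csv_path)
}

#' @rdname write_trial_dataset
#' @export
read_trial_dataset <- function(csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  data <- read.csv(csv_path, stringsAsFactors = FALSE)
  out <- list(data = data)
  if (file.exists(json_path)) {
    side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    truth <- list(state_sequence = side$state_sequence)
    if (!is.null(side$params)) {
      p <- side$params
      as_mat <- function(x, nr, nc) {
        if (is.matrix(x)) x else matrix(unlist(x), nr, nc, byrow = TRUE)
      }
      truth$params <- mslr_params(
        as_mat(p$transitions, p$n_states, p$n_states),
        as_mat(p$weights, p$n_states, p$n_features),
        p$biases, p$emission_vars, alpha = p$alpha, beta = p$beta)
    }
    out$truth <- truth
  }
  out
}
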