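#' Construct a Markov-switching linear regression parameter set
#'
#' Bundles the parameters of an MSLR: a row-stochastic transition matrix
#' over the latent states, per-state regression weights and biases mapping
#' the feature vector to the expected emission (reaction time), per-state
#' emission variances, and the sticky-Dirichlet transition hyperparameters
#' (concentration `alpha`, applied to every entry of a row, and stickiness
#' `beta`, added to the diagonal entry).
#'
#' @param transitions S x S row-stochastic matrix of state transition
#'   probabilities.
#' @param weights S x M matrix of per-state regression weights.
#' @param biases length-S vector of per-state intercepts.
#' @param emission_vars length-S vector of positive emission variances
#'   (squared RT units).
#' @param alpha,beta non-negative Dirichlet pseudo-counts: row concentration
#'   and diagonal stickiness of the transition prior.
#' @return An object of class `mslr_params` with elements `n_states`,
#'   `n_features`, `transitions`, `weights`, `biases`, `emission_vars`,
#'   `alpha`, `beta`.
#' @export
mslr_params <- function(transitions, weights, biases, emission_vars,
                        alpha = 1, beta = 1) {
  transitions <- as.matrix(transitions)
  weights <- as.matrix(weights)
  S <- nrow(transitions)
  if (ncol(transitions) != S) stop_invalid("transition matrix must be square")
  if (nrow(weights) != S) {
    stop_invalid("weights must have one row per state (%d), got %d",
                 S, nrow(weights))
  }
  if (length(biases) != S || length(emission_vars) != S) {
    stop_invalid("biases and emission_vars must have length S = %d", S)
  }
  if (any(emission_vars <= 0)) stop_invalid("emission variances must be > 0")
  if (any(transitions < 0) ||
      any(abs(rowSums(transitions) - 1) > 1e-10)) {
    stop_invalid("transition rows must be non-negative and sum to 1")
  }
  if (alpha < 0 || beta < 0) stop_invalid("alpha and beta must be >= 0")
  structure(
    list(n_states = S, n_features = ncol(weights),
         transitions = transitions, weights = weights,
         biases = as.numeric(biases), emission_vars = as.numeric(emission_vars),
         alpha = alpha, beta = beta),
    class = "mslr_params")
}

#' @export
print.mslr_params <- function(x, ...) {
  cat(sprintf("MSLR parameters: %d states, %d features\n",
              x$n_states, x$n_features))
  cat(sprintf("  alpha = %.3g, beta = %.3g\n", x$alpha, x$beta))
  cat(sprintf("  mean self-transition = %.3f\n", mean(diag(x$transitions))))
  cat(sprintf("  emission sd range = [%.3g, %.3g]\n",
              sqrt(min(x$emission_vars)), sqrt(max(x$emission_vars))))
  invisible(x)
}

#' Serialise / restore MSLR parameters as JSON
#'
#' Arrays are written shape-tagged so round-trips are lossless; fit
#' metadata (seed, likelihood trace) is preserved when present.
#'
#' @param params an [mslr_params] object, or an `mslr_fit` whose `params`
#'   element is written together with its trace and seed.
#' @param path file path to write to / read from.
#' @return `write_mslr_json` returns `path` invisibly; `read_mslr_json`
#'   returns an [mslr_params] object (with attribute `meta` holding any fit
#'   metadata found).
#' @export
write_mslr_json <- function(params, path) {
  meta <- NULL
  if (inherits(params, "mslr_fit")) {
    meta <- list(seed = params$seed, loglik = params$loglik,
                 trace = params$trace)
    params <- params$params
  }
  stopifnot(inherits(params, "mslr_params"))
  payload <- list(
    n_states = params$n_states, n_features = params$n_features,
    transitions = params$transitions, weights = params$weights,
    biases = params$biases, emission_vars = params$emission_vars,
    alpha = params$alpha, beta = params$beta, meta = meta)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mslr_json
#' @export
read_mslr_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), nr, nc, byrow = TRUE)
  }
  out <- mslr_params(
    transitions = as_mat(p$transitions, p$n_states, p$n_states),
    weights = as_mat(p$weights, p$n_states, p$n_features),
    biases = p$biases, emission_vars = p$emission_vars,
    alpha = p$alpha, beta = p$beta)
  attr(out, "meta") <- p$meta
  out
}
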