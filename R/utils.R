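# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. `seed = NULL` leaves the
# global stream untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# the 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  # double arithmetic: products stay exact below 2^53, result below 2^31
  (as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2147483629
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Column names of the feature block in a trial data frame.
feature_cols <- function(data) {
  grep("^x_[0-9]+$", names(data), value = TRUE)
}

feature_matrix <- function(data) {
  cols <- feature_cols(data)
  if (length(cols) == 0L) stop_invalid("no feature columns (x_1 ... x_M) found")
  as.matrix(data[, cols, drop = FALSE])
}

# One-hot encode an integer state sequence into a T x S indicator matrix.
one_hot_states <- function(states, n_states) {
  stopifnot(all(states >= 1L), all(states <= n_states))
  out <- matrix(0, length(states), n_states)
  out[cbind(seq_along(states), states)] <- 1
  out
}

# Maximum-weight one-to-one assignment of columns to rows of `score`
# (n x m, n <= m): exhaustive over permutations for small problems, greedy
# otherwise. Returns the column index assigned to each row.
match_states <- function(score) {
  n <- nrow(score)
  m <- ncol(score)
  stopifnot(n <= m)
  if (m <= 8L) {
    perms <- permutations_of(seq_len(m), n)
    best <- NULL
    best_val <- -Inf
    for (i in seq_len(nrow(perms))) {
      val <- sum(score[cbind(seq_len(n), perms[i, ])])
      if (val > best_val) {
        best_val <- val
        best <- perms[i, ]
      }
    }
    return(best)
  }
  # greedy fallback for large problems
  assign <- integer(n)
  free <- rep(TRUE, m)
  ord <- order(apply(score, 1L, max), decreasing = TRUE)
  for (i in ord) {
    j <- which.max(ifelse(free, score[i, ], -Inf))
    assign[i] <- j
    free[j] <- FALSE
  }
  assign
}

# All ordered arrangements of `k` elements from `x` (rows).
permutations_of <- function(x, k) {
  if (k == 0L) return(matrix(integer(0), 1L, 0L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i], k - 1L)
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# Coefficient of determination on held-out observations.
r_squared <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}
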