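# State characterisation: transitions, dwell times, certainty, stochastic
# superiority, histograms, Jensen-Shannon clustering, decoding, template
# matching, trial-history baseline.

test_that("empirical transitions are row-normalised bigram counts", {
  m <- empirical_transition_matrix(c(1, 1, 1, 2, 2), 2)
  expect_equal(m[1, ], c(2 / 3, 1 / 3))
  expect_equal(m[2, ], c(0, 1))
  # constant sequence: identity row for that state, uniform for unseen
  m2 <- empirical_transition_matrix(rep(1, 5), 2)
  expect_equal(m2[1, ], c(1, 0))
  expect_equal(m2[2, ], c(0.5, 0.5))
  # transitions across session boundaries are not counted
  m3 <- empirical_transition_matrix(c(1, 1, 2, 2), 2,
                                    sessions = c(1, 1, 2, 2))
  expect_equal(m3[1, ], c(1, 0))
})

test_that("dwell times are maximal runs bounded by sessions", {
  dw <- dwell_times(c(1, 1, 1, 2, 2))
  expect_identical(dw[["1"]], 3L)
  expect_identical(dw[["2"]], 2L)
  # conservation: run lengths sum to the sequence length
  set.seed(1)
  z <- sample(1:3, 200, replace = TRUE)
  expect_identical(sum(unlist(dwell_times(z))), 200L)
  expect_identical(dwell_times(rep(2L, 17))[["2"]], 17L)
  # a session boundary splits an otherwise single run
  dw2 <- dwell_times(c(1, 1, 1, 1), sessions = c(1, 1, 2, 2))
  expect_identical(dw2[["1"]], c(2L, 2L))
})

test_that("normalised KL certainty spans [0, 1] with known endpoints", {
  expect_equal(state_certainty_kl(rep(1 / 4, 4)), 0, tolerance = 1e-12)
  expect_equal(state_certainty_kl(c(1, 0, 0)), 1, tolerance = 1e-12)
  # direct entropy computation for a 2-state row
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(state_certainty_kl(c(0.9, 0.1)), (log(2) - h) / log(2),
               tolerance = 1e-12)
  expect_equal(round(state_certainty_kl(c(0.9, 0.1)), 3), 0.531)
  # property: any simplex row lands in [0, 1]
  set.seed(2)
  for (i in 1:50) {
    p <- rgamma(4, 1)
    p <- p / sum(p)
    v <- state_certainty_kl(p)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_error(state_certainty_kl(1), "single state")
})

test_that("stochastic superiority matches explicit pair counting", {
  expect_equal(vargha_delaney_omega(c(1, 2, 3), c(1, 2, 3))$omega, 0.5)
  expect_equal(vargha_delaney_omega(1:5, 10:14)$omega, 1)
  # tie-rich case against the brute-force oracle
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  res <- vargha_delaney_omega(a, b)
  expect_equal(res$A, brute_force_A(a, b), tolerance = 1e-12)
  expect_equal(res$omega, max(res$A, 1 - res$A))
  set.seed(3)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 9, replace = TRUE)
    expect_equal(vargha_delaney_omega(x, y)$A, brute_force_A(x, y),
                 tolerance = 1e-12)
    # symmetry of the folded measure
    expect_equal(vargha_delaney_omega(x, y)$omega,
                 vargha_delaney_omega(y, x)$omega, tolerance = 1e-12)
    # invariance under a common strictly monotone transform
    expect_equal(vargha_delaney_omega(exp(x), exp(y))$omega,
                 vargha_delaney_omega(x, y)$omega, tolerance = 1e-12)
  }
})

test_that("omega bands follow the conventional cutoffs", {
  expect_identical(as.character(omega_band(c(0.5, 0.58, 0.66, 0.8))),
                   c("negligible", "small", "medium", "high"))
})

test_that("face separability tables cover all feature-state pairs", {
  set.seed(4)
  feats <- data.frame(f1 = rnorm(90), f2 = rnorm(90, sd = 2))
  states <- rep(1:3, each = 30)
  tab <- face_separability(feats, states)
  expect_identical(nrow(tab), 2L * 3L)  # 2 features x 3 state pairs
  expect_true(all(tab$omega >= 0.5 & tab$omega <= 1))
})

test_that("Freedman-Diaconis histograms share edges and sum to one", {
  set.seed(5)
  vals <- list(a = rnorm(300), b = rnorm(400, 2))
  hs <- state_emission_histograms(vals)
  expect_equal(rowSums(hs$histograms), c(a = 1, b = 1), tolerance = 1e-12)
  # identical samples give identical histograms
  hs2 <- state_emission_histograms(list(vals$a, vals$a))
  expect_equal(hs2$histograms[1, ], hs2$histograms[2, ])
  # the pooled FD width for 1000 uniforms: 2 * IQR * n^(-1/3), IQR ~ 0.5
  u <- runif(1000)
  hu <- state_emission_histograms(list(u[1:500], u[501:1000]))
  expect_equal(hu$bin_width, 2 * IQR(u) * 1000^(-1 / 3), tolerance = 1e-12)
  expect_equal(hu$bin_width, 0.1, tolerance = 0.02)
  # degenerate spread falls back instead of failing
  expect_warning(state_emission_histograms(list(rep(1, 10), rep(1, 10))),
                 "IQR")
})

test_that("Jensen-Shannon distance is a bounded metric on histograms", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_distance(p, p), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)  # disjoint support
  expect_error(js_distance(c(1, 0), c(0.5, 0.25, 0.25)), "support")
  set.seed(6)
  for (i in 1:20) {
    a <- rgamma(6, 1)
    a <- a / sum(a)
    b <- rgamma(6, 1)
    b <- b / sum(b)
    cc <- rgamma(6, 1)
    cc <- cc / sum(cc)
    expect_equal(js_distance(a, b), direct_js_distance(a, b),
                 tolerance = 1e-12)
    expect_equal(js_distance(a, b), js_distance(b, a), tolerance = 1e-12)
    expect_lte(js_distance(a, b), 1)
    # triangle inequality, sampled
    expect_lte(js_distance(a, cc),
               js_distance(a, b) + js_distance(b, cc) + 1e-12)
  }
})

test_that("state clustering merges duplicates and keeps distinct states", {
  set.seed(7)
  x <- rnorm(500)
  hs <- state_emission_histograms(list(x, x + rnorm(500, sd = 0.01),
                                       x + 10))
  groups <- cluster_states(hs$histograms, threshold = 0.5)
  expect_identical(groups[1], groups[2])
  expect_false(groups[3] == groups[1])
  # disjoint supports at a sub-unity threshold: all singletons
  hs2 <- state_emission_histograms(list(rnorm(200), rnorm(200) + 50,
                                        rnorm(200) - 50))
  expect_identical(length(unique(cluster_states(hs2$histograms, 0.9))), 3L)
})

test_that("outcome decoding finds planted state-outcome structure", {
  set.seed(8)
  n <- 600
  z <- sample(1:3, n, replace = TRUE)
  post <- matrix(0.05, n, 3)
  post[cbind(1:n, z)] <- 0.9
  # chance when outcomes ignore the states
  dec0 <- decode_outcome(post, sample(c("hit", "wrong", "miss"), n,
                                      replace = TRUE), seed = 9)
  expect_lt(abs(dec0$balanced_accuracy - 1 / 3), 0.1)
  # deterministic mapping from argmax state to outcome
  dec1 <- decode_outcome(post, c("hit", "wrong", "miss")[z], seed = 10)
  expect_gt(dec1$balanced_accuracy, 0.95)
  # planted association: state 2 yields hits with probability 0.9
  out <- ifelse(z == 2 & runif(n) < 0.9, "hit", "miss")
  dec2 <- decode_outcome(post, out, seed = 11)
  expect_identical(unname(which.max(dec2$weights[, "hit"])), 2L)
  expect_error(decode_outcome(post, rep("hit", n)), "2 outcome classes")
})

test_that("template matching separates planted feature clusters", {
  set.seed(12)
  # distinct facial patterns per state, well above the noise
  centers <- matrix(c(0, 5, 0, 5, 0,
                      5, 0, 5, 0, 5,
                      5, 5, 0, 0, 5), 3, 5, byrow = TRUE)
  z <- rep(1:3, each = 40)
  feats <- centers[z, ] + matrix(rnorm(600, sd = 0.3), 120)
  train <- which(seq_len(120) %% 2 == 0)
  res <- template_match(feats, z, train)
  expect_gte(res$accuracy, 0.95)
  # identical templates: accuracy falls to chance
  flat <- matrix(rnorm(600), 120)
  res0 <- template_match(flat, z, train)
  expect_lt(res0$accuracy, 0.65)
  # training trials of a one-trial-per-state set classify themselves
  one <- matrix(c(0, 1, 0, 5, 5, 1, 9, 0, 4), 3, byrow = TRUE)
  res1 <- template_match(one, 1:3, train_idx = 1:3, test_idx = 1:3)
  expect_equal(res1$accuracy, 1)
})

test_that("the trial-history baseline tracks RT autocorrelation", {
  # white-noise reaction times: nothing to exploit
  set.seed(13)
  d_white <- data.frame(session = 1, rt = rnorm(800))
  ar_white <- fit_arhmm_baseline(d_white, n_states = 1, seed = 14,
                                 n_iter = 5, n_restarts = 1, k = 3)
  expect_lt(ar_white$cv$mean_r2, 0.05)
  # AR(1) reaction times at 0.9: predictability ~ 0.81
  rt <- numeric(2000)
  rt[1] <- rnorm(1)
  for (t in 2:2000) rt[t] <- 0.9 * rt[t - 1] + rnorm(1, sd = sqrt(1 - 0.81))
  d_ar <- data.frame(session = 1, rt = rt)
  ar_fit <- fit_arhmm_baseline(d_ar, n_states = 1, seed = 15,
                               n_iter = 5, n_restarts = 1, k = 3)
  expect_equal(ar_fit$cv$mean_r2, 0.81, tolerance = 0.06)
})

test_that("feature-driven emissions beat the trial-history baseline", {
  fx <- make_recovery_fixture(1000, n_states = 3, n_features = 4,
                              noise_sd = 0.2, seed = 16)
  data <- fx$sim$data
  cv_face <- time_blocked_cv(data, 3, alpha = 1, beta = 20, k = 3,
                             reps = 1, seed = 17, n_iter = 20,
                             n_restarts = 2)
  ar <- fit_arhmm_baseline(data, n_states = 3, alpha = 1, beta = 20,
                           seed = 18, n_iter = 20, n_restarts = 2, k = 3)
  expect_gt(cv_face$mean_r2, ar$cv$mean_r2)
})
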