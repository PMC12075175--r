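# Independent brute-force oracles: literal summation implementations of the
# descriptor formulas and exact enumeration of the rank statistics. These
# deliberately share no code with the package internals.

oracle_isd <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + x[i] * x[i]
  s
}

oracle_isd_rsc <- function(x, order, theta) {
  n <- length(x)
  dd <- if (order == 1) {
    vapply(seq_len(n - 1), function(i) x[i + 1] - x[i], 0)
  } else {
    vapply(seq_len(n - 2), function(i) x[i + 2] - 2 * x[i + 1] + x[i], 0)
  }
  oracle_isd(x) - sum(dd ^ 2) / theta
}

oracle_log_kernel <- function(x, eps) {
  s <- 0
  for (i in seq_along(x)) s <- s + log(abs(x[i]) + eps)
  abs(exp(s / length(x)))
}

oracle_mean_sqrt <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + sqrt(abs(x[i]))
  s / length(x)
}

oracle_mean_dd2 <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 2)) s <- s + x[i + 2] - 2 * x[i + 1] + x[i]
  s / n
}

oracle_all_features <- function(x, theta = length(x), eps = 1e-8) {
  c(oracle_isd(x),
    oracle_isd_rsc(x, 1, theta),
    oracle_isd_rsc(x, 2, theta),
    oracle_log_kernel(x, eps),
    oracle_mean_sqrt(x),
    oracle_mean_dd2(x))
}

# exact signed-rank p by enumeration of all 2^n sign patterns
oracle_signrank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  switch(alternative,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs),
         two.sided = {
           p <- if (v_obs > n * (n + 1) / 4) mean(v_all >= v_obs)
                else mean(v_all <= v_obs)
           min(1, 2 * p)
         })
}

# Friedman chi-square from the textbook rank formula (no ties)
oracle_friedman_chisq <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  colsum <- colSums(R)
  12 / (n * k * (k + 1)) * sum(colsum ^ 2) - 3 * n * (k + 1)
}

# brute-force overlapping-window enumeration
oracle_window_count <- function(n, L, S) {
  count <- 0L
  start <- 1L
  while (start + L - 1L <= n) {
    count <- count + 1L
    start <- start + S
  }
  count
}

# small cached fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_session <- function() {
  if (is.null(.fixture_env$tiny)) {
    p <- emg_protocol(reps_per_gesture = 2L, move_s = 1.5, rest_s = 0.8,
                      seed = 11L)
    .fixture_env$tiny <- list(protocol = p,
                              rec = generate_session(p))
  }
  .fixture_env$tiny
}

tiny_features <- function() {
  if (is.null(.fixture_env$feats)) {
    ts <- tiny_session()
    rec <- apply_filter_chain(ts$rec)
    .fixture_env$feats <- extract_feature_tensor(
      rec, window_spec(fs = ts$protocol$fs), time_steps = 10L)
  }
  .fixture_env$feats
}
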