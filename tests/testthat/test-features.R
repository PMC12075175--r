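test_that("descriptor features match hand-computed values", {
  expect_equal(feature_isd(c(1, 2, 3)), 14)
  expect_equal(feature_isd(rep(0, 10)), 0)
  expect_equal(feature_isd_minus_rsc(c(1, 2, 4), 1, theta = 3),
               21 - (1 + 4) / 3)
  expect_equal(feature_isd_minus_rsc(c(1, 2, 4), 2, theta = 3), 21 - 1 / 3)
  # constant window: difference terms vanish
  x <- rep(2.5, 8)
  expect_equal(feature_isd_minus_rsc(x, 1), feature_isd(x))
  expect_equal(feature_isd_minus_rsc(x, 2), feature_isd(x))
  expect_equal(feature_mean_log_kernel(rep(exp(1), 3)), exp(1),
               tolerance = 1e-6)
  expect_equal(feature_mean_log_kernel(c(1, 4)), 2, tolerance = 1e-6)
  expect_equal(feature_mean_sqrt(c(4, 9)), 2.5)
  expect_equal(feature_mean_sqrt(c(-4, -9)), 2.5)  # magnitude convention
  expect_equal(feature_mean_sqrt(rep(0, 5)), 0)
  expect_equal(feature_mean_dd2(c(0, 1, 2, 3)), 0)
  expect_equal(feature_mean_dd2(c(0, 0, 1)), 1 / 3)
  expect_equal(feature_mean_dd2((0:4) ^ 2), 6 / 5)
})

test_that("features agree with brute-force oracles on random windows", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:50, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    got <- c(feature_isd(x),
             feature_isd_minus_rsc(x, 1), feature_isd_minus_rsc(x, 2),
             feature_mean_log_kernel(x), feature_mean_sqrt(x),
             feature_mean_dd2(x))
    want <- oracle_all_features(x)
    worst <- max(worst, abs(got - want) / pmax(abs(want), 1e-300))
  }
  expect_lt(worst, 1e-10)
})

test_that("feature symmetries hold on random windows", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(30)
    a <- runif(1, 0.1, 5)
    expect_equal(feature_isd(a * x), a ^ 2 * feature_isd(x))
    expect_equal(feature_mean_log_kernel(-x), feature_mean_log_kernel(x))
    expect_equal(feature_mean_sqrt(-x), feature_mean_sqrt(x))
  }
})

test_that("the sliding extractor equals per-window scalar evaluation", {
  set.seed(9)
  x <- rnorm(1500)
  starts <- seq(1, 1100, by = 17)
  L <- 60
  fast <- emgband:::.channel_features(x, starts, L, theta = L,
                                      eps_log = 1e-8)
  slow <- t(vapply(starts, function(s) oracle_all_features(x[s:(s + L - 1)],
                                                           theta = L),
                   numeric(6)))
  expect_equal(fast, slow, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the feature tensor has the documented geometry and labels", {
  wf <- tiny_features()
  d <- dim(wf$tensor)
  expect_equal(d[2], 10L)          # time steps requested
  expect_equal(d[3], 21L)          # channels
  expect_equal(d[4], 6L)           # features
  expect_true(all(is.finite(wf$tensor)))
  expect_equal(length(wf$labels), d[1])
  expect_equal(nrow(wf$window_labels), d[1])
  # single-gesture segment of 890 samples yields exactly one model sample
  p <- tiny_session()$protocol
  one <- emg_recording(tiny_session()$rec$data[1:890, ], p$fs,
                       rep(2L, 890), meta = list(rest_id = 6L))
  wf1 <- extract_feature_tensor(one,
                                window_spec(length_samples = 300,
                                            step_samples = 10, fs = p$fs),
                                time_steps = 60L)
  expect_equal(dim(wf1$tensor), c(1L, 60L, 21L, 6L))
  expect_equal(wf1$labels, 2L)

  # rest-only recording: everything labeled rest
  ro <- emg_recording(matrix(rnorm(2000 * 2), 2000, 2), p$fs,
                      rep(6L, 2000), meta = list(rest_id = 6L))
  wfr <- extract_feature_tensor(ro, window_spec(length_samples = 100,
                                                step_samples = 10,
                                                fs = p$fs),
                                time_steps = 5L)
  expect_true(all(wfr$labels == 6L))

  expect_error(extract_feature_tensor(ro,
                                      window_spec(length_samples = 100,
                                                  step_samples = 10,
                                                  fs = p$fs),
                                      time_steps = 10000L), "too short")
})

test_that("features of one channel depend only on that channel", {
  ts <- tiny_session()
  rec <- ts$rec
  sub <- emg_recording(rec$data[1:3000, 1:4], rec$fs, rec$labels[1:3000],
                       meta = list(rest_id = 6L))
  ws <- window_spec(length_samples = 200, step_samples = 20, fs = rec$fs)
  a <- extract_feature_tensor(sub, ws, time_steps = 5L)
  perm <- c(2, 4, 1, 3)
  subp <- emg_recording(sub$data[, perm], rec$fs, sub$labels,
                        meta = list(rest_id = 6L))
  b <- extract_feature_tensor(subp, ws, time_steps = 5L)
  expect_equal(a$tensor[, , perm, ], b$tensor, tolerance = 1e-12)
})

test_that("standardization yields zero-mean unit-variance training features", {
  wf <- tiny_features()
  std <- standardize_features(wf)
  m <- apply(std$tensor, c(3, 4), mean)
  s <- apply(std$tensor, c(3, 4), sd)
  expect_lt(max(abs(m)), 1e-6)
  expect_lt(max(abs(s - 1)), 1e-6)
  # applying saved stats to the same tensor reproduces the standardization
  std2 <- standardize_features(wf, stats = attr(std, "standardization"))
  expect_equal(std2$tensor, std$tensor)
})

test_that("feature configuration is validated", {
  expect_error(feature_config(theta = 0), "theta")
  expect_error(feature_config(eps_log = 0), "eps_log")
  expect_error(feature_isd(numeric(0)), "empty")
  expect_error(feature_isd_minus_rsc(c(1, 2), 1), "short")
  expect_error(feature_isd_minus_rsc(1:5, 3), "order")
})
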