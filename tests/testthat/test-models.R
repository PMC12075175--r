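# small separable feature tensors: class k raises the mean of channel k
toy_tensor <- function(N = 120L, T_ = 8L, C = 6L, F_ = 4L, K = 6L,
                       effect = 1, seed = 1L) {
  set.seed(seed)
  X <- array(rnorm(N * T_ * C * F_, sd = 0.3), c(N, T_, C, F_))
  y <- rep(seq_len(K), length.out = N)
  for (i in seq_len(N)) {
    ch <- ((y[i] - 1L) %% C) + 1L
    X[i, , ch, ] <- X[i, , ch, ] + effect
  }
  list(X = X, y = y)
}

fast_cfg <- function(...) {
  args <- list(n_blocks = 2L, dilations = c(1L, 2L), filters = 6L,
               dropout_p = 0, epochs = 15L, patience = 15L, lr = 1e-2)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(stcn_config, args)
}

test_that("LDA separates well-separated Gaussian classes near Bayes rate", {
  set.seed(3)
  n <- 200
  X <- rbind(matrix(rnorm(n, mean = 1), n / 2, 2),
             matrix(rnorm(n, mean = -1), n / 2, 2))
  y <- rep(1:2, each = n / 2)
  fit <- emgband:::.lda_fit(X, y)
  pred <- fit$classes[max.col(emgband:::.lda_probs(fit, X))]
  # Bayes accuracy for unit-variance classes at means +-(1,1):
  # pnorm(||mu1 - mu2|| / 2) = pnorm(sqrt(2)) ~ 0.921
  expect_gte(mean(pred == y), pnorm(sqrt(2)) - 0.03)
  # cross-check against the classical reference implementation
  skip_if_not_installed("MASS")
  m <- MASS::lda(X, grouping = factor(y))
  pm <- as.integer(predict(m, X)$class)
  expect_gte(mean(pred == pm), 0.98)
})

test_that("LDA degenerate inputs behave as specified", {
  X <- matrix(rnorm(100), 50, 2)
  expect_error(emgband:::.lda_fit(X, rep(1L, 50)), "two classes")
  # duplicated feature columns: singular covariance, shrinkage rescues
  Xd <- cbind(X, X[, 1])
  y <- rep(1:2, 25)
  fit <- suppressWarnings(emgband:::.lda_fit(Xd, y))
  expect_true(is.finite(sum(fit$W)))
})

test_that("decoders emit proper probability vectors and class predictions", {
  toy <- toy_tensor(N = 60L)
  for (kind in c("lda", "tcn", "stcn")) {
    dec <- fit_decoder(toy$X, toy$y, kind = kind,
                       config = if (kind == "lda") NULL else fast_cfg(),
                       seed = 2L)
    p <- predict(dec, toy$X, type = "prob")
    expect_equal(dim(p), c(60L, 6L))
    expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-6)
    expect_true(all(p >= 0))
    cls <- predict(dec, toy$X)
    expect_true(all(cls %in% 1:6))
  }
})

test_that("network training is deterministic under a fixed seed", {
  toy <- toy_tensor(N = 40L)
  cfg <- fast_cfg(dropout_p = 0.2, epochs = 4L)
  d1 <- fit_decoder(toy$X, toy$y, kind = "stcn", config = cfg, seed = 9L)
  d2 <- fit_decoder(toy$X, toy$y, kind = "stcn", config = cfg, seed = 9L)
  expect_identical(serialize(d1$net$params, NULL),
                   serialize(d2$net$params, NULL))
  d3 <- fit_decoder(toy$X, toy$y, kind = "stcn", config = cfg, seed = 10L)
  expect_false(identical(serialize(d1$net$params, NULL),
                         serialize(d3$net$params, NULL)))
})

test_that("networks fit separable data and stay at chance on shuffled labels", {
  toy <- toy_tensor(N = 150L, effect = 1.5)
  dec <- fit_decoder(toy$X, toy$y, kind = "stcn", config = fast_cfg(),
                     seed = 4L)
  expect_gte(mean(predict(dec, toy$X) == toy$y), 0.95)

  set.seed(99)
  ysh <- sample(toy$y)
  dsh <- fit_decoder(toy$X, ysh, kind = "stcn",
                     config = fast_cfg(epochs = 8L), seed = 4L)
  # held-out-style check: accuracy on fresh permuted labels ~ 1/6
  acc <- mean(predict(dsh, toy$X) == sample(ysh))
  expect_lt(abs(acc - 1 / 6), 0.08)
})

test_that("temporal convolutions are causal (no future leakage)", {
  cfg <- fast_cfg()
  set.seed(5)
  for (builder in list(build_stcn, build_vanilla_tcn)) {
    net <- builder(cfg, c(12L, 5L, 3L), 4L)
    X <- array(rnorm(12 * 5 * 3), c(1L, 12L, 5L, 3L))
    f1 <- emgband:::.nn_forward(net, X, train = FALSE, keep_cache = TRUE)
    X2 <- X
    X2[1, 9:12, , ] <- X2[1, 9:12, , ] + 5
    f2 <- emgband:::.nn_forward(net, X2, train = FALSE, keep_cache = TRUE)
    for (b in 1:2) {
      a1 <- f1$caches[[b]]$out
      a2 <- f2$caches[[b]]$out
      expect_equal(a1[, 1:8, , , drop = FALSE], a2[, 1:8, , , drop = FALSE])
      expect_false(isTRUE(all.equal(a1, a2)))
    }
  }
})

test_that("gradient of the output w.r.t. future inputs is exactly zero", {
  cfg <- fast_cfg()
  set.seed(6)
  net <- build_stcn(cfg, c(10L, 4L, 3L), 3L)
  X <- array(rnorm(10 * 4 * 3), c(1L, 10L, 4L, 3L))
  # gradient of the logit at a sequence truncated after t: positions > t in
  # the pooled head DO contribute; test the temporal block instead by
  # differentiating an early-time activation through the input
  fwd <- emgband:::.nn_forward(net, X, train = FALSE, keep_cache = TRUE)
  eps <- 1e-6
  Xp <- X
  Xp[1, 10, 1, 1] <- Xp[1, 10, 1, 1] + eps
  f2 <- emgband:::.nn_forward(net, Xp, train = FALSE, keep_cache = TRUE)
  dact <- (f2$caches[[2]]$out[1, 1:9, , ] - fwd$caches[[2]]$out[1, 1:9, , ])
  expect_equal(max(abs(dact)), 0)
})

test_that("a matched spatial-branch-free network has strictly fewer parameters", {
  cfg <- fast_cfg(channel_mode = "independent")
  stcn <- build_stcn(cfg, c(10L, 21L, 6L), 6L)
  tcn <- build_vanilla_tcn(cfg, c(10L, 21L, 6L), 6L)
  expect_lt(emgband:::.nn_n_params(tcn), emgband:::.nn_n_params(stcn))
})

test_that("channel-independent TCN is invariant to channel permutation", {
  cfg <- fast_cfg(channel_mode = "independent")
  set.seed(7)
  net <- build_vanilla_tcn(cfg, c(8L, 6L, 4L), 3L)
  X <- array(rnorm(2 * 8 * 6 * 4), c(2L, 8L, 6L, 4L))
  p1 <- emgband:::.nn_predict(net, X)
  perm <- sample(6)
  p2 <- emgband:::.nn_predict(net, X[, , perm, , drop = FALSE])
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the spatial branch mixes information across channels", {
  cfg <- fast_cfg()
  set.seed(8)
  net <- build_stcn(cfg, c(8L, 6L, 4L), 3L)
  X <- array(rnorm(8 * 6 * 4), c(1L, 8L, 6L, 4L))
  g <- emgband:::.nn_input_grad(net, X, 1L)
  # untrained stcn already propagates gradient to every channel
  ch_grad <- apply(abs(g[1, , , ]), 2, sum)
  expect_true(all(ch_grad > 0))
  # the channel-independent vanilla network pools channels symmetrically, so
  # permuting channels permutes its input gradient
  neti <- build_vanilla_tcn(fast_cfg(channel_mode = "independent"),
                            c(8L, 6L, 4L), 3L)
  gi <- emgband:::.nn_input_grad(neti, X, 1L)
  perm <- c(3, 1, 2, 6, 5, 4)
  gp <- emgband:::.nn_input_grad(neti, X[, , perm, , drop = FALSE], 1L)
  expect_equal(gi[1, , perm, ], gp[1, , , ], tolerance = 1e-10)
})

test_that("spatially-coded classes favour the spatio-temporal network", {
  res <- spatial_advantage_experiment(n_seeds = 3L, seed = 42L)
  expect_true(all(res$acc$stcn >= res$acc$tcn))
  expect_gt(mean(res$acc$stcn - res$acc$tcn), 0.1)
})

test_that("training aborts on divergence and validates inputs", {
  toy <- toy_tensor(N = 30L)
  set.seed(1)
  net <- build_stcn(fast_cfg(), c(8L, 6L, 4L), 6L)
  net$params$head$W[1, 1] <- NaN
  expect_error(emgband:::.nn_train(net, toy$X, toy$y, epochs = 2L),
               "diverged")
  expect_error(stcn_config(dropout_p = 1), "dropout_p")
  expect_error(stcn_config(spatial_kernel = 4L), "odd")
  expect_error(build_stcn(stcn_config(spatial_kernel = 9L),
                          c(10L, 5L, 3L), 4L), "spatial_kernel")
})
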