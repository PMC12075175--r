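# Minimal convolutional-network engine for the gesture decoders.
#
# Tensors are base-R arrays [N, T, C, F] (samples, time steps, channels,
# features; F is the last = slowest dimension, so matrix(X, ncol = F) views
# the tensor as (N*T*C) x F with features as columns). All forward/backward
# passes are hand-derived; randomness (init, shuffling, dropout) comes from
# the R RNG so a fixed seed reproduces training bit-for-bit.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# shift along the time axis; s > 0 delays (zero padding at the start,
# causal), s < 0 advances
.shift_t <- function(X, s) {
  if (s == 0) return(X)
  d <- dim(X)
  Y <- array(0, d)
  if (abs(s) >= d[2]) return(Y)
  if (s > 0) Y[, (s + 1):d[2], , ] <- X[, 1:(d[2] - s), , , drop = FALSE]
  else Y[, 1:(d[2] + s), , ] <- X[, (1 - s):d[2], , , drop = FALSE]
  Y
}

.mat <- function(X) {
  d <- dim(X)
  matrix(X, ncol = d[length(d)])
}

# causal dilated convolution along time, shared across channels
.tconv_fwd <- function(X, W, b, dil) {
  d <- dim(X); K <- dim(W)[1]; Fin <- dim(W)[2]; Fout <- dim(W)[3]
  Ym <- matrix(rep(b, each = d[1] * d[2] * d[3]), ncol = Fout)
  for (k in seq_len(K)) {
    Xs <- if (k == 1) X else .shift_t(X, (k - 1) * dil)
    Ym <- Ym + .mat(Xs) %*% matrix(W[k, , ], Fin, Fout)
  }
  array(Ym, c(d[1], d[2], d[3], Fout))
}

.tconv_bwd <- function(dY, X, W, dil) {
  d <- dim(X); K <- dim(W)[1]; Fin <- dim(W)[2]; Fout <- dim(W)[3]
  dYm <- .mat(dY)
  dW <- array(0, dim(W))
  dX <- array(0, d)
  for (k in seq_len(K)) {
    s <- (k - 1) * dil
    Xs <- if (s == 0) X else .shift_t(X, s)
    dW[k, , ] <- crossprod(.mat(Xs), dYm)
    dXs <- array(dYm %*% t(matrix(W[k, , ], Fin, Fout)), d)
    dX <- dX + (if (s == 0) dXs else .shift_t(dXs, -s))
  }
  list(dX = dX, dW = dW, db = colSums(dYm))
}

# circular convolution across the channel axis at each time step
.sconv_fwd <- function(X, W, b) {
  d <- dim(X); S <- dim(W)[1]; Fin <- dim(W)[2]; Fout <- dim(W)[3]
  h <- (S - 1L) %/% 2L
  C <- d[3]
  Ym <- matrix(rep(b, each = d[1] * d[2] * d[3]), ncol = Fout)
  for (j in seq_len(S)) {
    off <- j - 1L - h
    idx <- ((seq_len(C) - 1L + off) %% C) + 1L
    Xs <- X[, , idx, , drop = FALSE]
    Ym <- Ym + .mat(Xs) %*% matrix(W[j, , ], Fin, Fout)
  }
  array(Ym, c(d[1], d[2], d[3], Fout))
}

.sconv_bwd <- function(dY, X, W) {
  d <- dim(X); S <- dim(W)[1]; Fin <- dim(W)[2]; Fout <- dim(W)[3]
  h <- (S - 1L) %/% 2L; C <- d[3]
  dYm <- .mat(dY)
  dW <- array(0, dim(W))
  dX <- array(0, d)
  for (j in seq_len(S)) {
    off <- j - 1L - h
    idx <- ((seq_len(C) - 1L + off) %% C) + 1L
    Xs <- X[, , idx, , drop = FALSE]
    dW[j, , ] <- crossprod(.mat(Xs), dYm)
    dXp <- array(dYm %*% t(matrix(W[j, , ], Fin, Fout)), d)
    dX[, , idx, ] <- dX[, , idx, , drop = FALSE] + dXp
  }
  list(dX = dX, dW = dW, db = colSums(dYm))
}

.bn_fwd <- function(X, p, state, train) {
  M <- .mat(X)
  if (train) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    v <- colMeans(xc ^ 2)
    xhat <- sweep(xc, 2, sqrt(v + .BN_EPS), "/")
    state$rmean <- (1 - .BN_MOMENTUM) * state$rmean + .BN_MOMENTUM * mu
    state$rvar <- (1 - .BN_MOMENTUM) * state$rvar + .BN_MOMENTUM * v
    cache <- list(xhat = xhat, var = v)
  } else {
    xhat <- sweep(sweep(M, 2, state$rmean), 2, sqrt(state$rvar + .BN_EPS), "/")
    cache <- list(var = state$rvar)
  }
  Y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(Y = array(Y, dim(X)), state = state, cache = cache)
}

.bn_bwd_train <- function(dY, cache, gamma) {
  dYm <- .mat(dY)
  xhat <- cache$xhat
  m <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, "*")
  inv <- 1 / sqrt(cache$var + .BN_EPS)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dYm), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), m, ncol(dYm),
                              byrow = TRUE),
              2, inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.bn_bwd_eval <- function(dY, gamma, rvar) {
  sweep(.mat(dY), 2, gamma / sqrt(rvar + .BN_EPS), "*")
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# ---- model construction ------------------------------------------------

# channel_mode: "spatial" (stcn), "flatten" (vanilla, channels folded into
# the feature axis), "independent" (vanilla, shared weights per channel and
# channel-agnostic pooling)
.nn_init <- function(input_shape, n_classes, cfg, channel_mode) {
  T_ <- input_shape[1]; C <- input_shape[2]; F0 <- input_shape[3]
  if (channel_mode == "flatten") { F0 <- C * F0; C <- 1L }
  if (channel_mode == "spatial" && cfg$spatial_kernel > C)
    stop("spatial_kernel larger than the channel count")
  blocks <- vector("list", cfg$n_blocks)
  bn_state <- vector("list", cfg$n_blocks)
  fin <- F0
  for (b in seq_len(cfg$n_blocks)) {
    fo <- cfg$filters
    blk <- list(t = list(
      W = .he_init(c(cfg$temporal_kernel, fin, fo),
                   cfg$temporal_kernel * fin),
      b = numeric(fo)))
    fmerged <- fo
    if (channel_mode == "spatial") {
      blk$s <- list(
        W = .he_init(c(cfg$spatial_kernel, fin, fo), cfg$spatial_kernel * fin),
        b = numeric(fo))
      fmerged <- if (cfg$merge == "concat") 2L * fo else fo
    }
    blk$bn <- list(gamma = rep(1, fmerged), beta = numeric(fmerged))
    bn_state[[b]] <- list(rmean = numeric(fmerged), rvar = rep(1, fmerged))
    blocks[[b]] <- blk
    fin <- fmerged
  }
  head_in <- if (channel_mode == "independent") fin else C * fin
  head <- list(W = .he_init(c(head_in, n_classes), head_in),
               b = numeric(n_classes))
  list(cfg = cfg, channel_mode = channel_mode,
       input_shape = input_shape, n_classes = n_classes,
       params = list(blocks = blocks, head = head),
       bn_state = bn_state)
}

.nn_n_params <- function(net) {
  cnt <- 0L
  walk <- function(x) {
    if (is.numeric(x)) cnt <<- cnt + length(x)
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(net$params)
  cnt
}

# ---- forward / backward ------------------------------------------------

.nn_forward <- function(net, X, train = FALSE, keep_cache = FALSE) {
  cfg <- net$cfg
  if (net$channel_mode == "flatten") {
    d <- dim(X)
    # column-major reshape folds (channel, feature) into one axis, channel
    # fastest, preserving element order
    dim(X) <- c(d[1], d[2], 1L, d[3] * d[4])
  }
  caches <- list()
  H <- X
  for (b in seq_len(cfg$n_blocks)) {
    blk <- net$params$blocks[[b]]
    dil <- cfg$dilations[min(b, length(cfg$dilations))]
    cache <- list(X = H)
    At <- .tconv_fwd(H, blk$t$W, blk$t$b, dil)
    if (net$channel_mode == "spatial") {
      As <- .sconv_fwd(H, blk$s$W, blk$s$b)
      M <- if (cfg$merge == "concat") {
        dm <- dim(At)
        arr <- array(0, c(dm[1], dm[2], dm[3], 2L * dm[4]))
        arr[, , , seq_len(dm[4])] <- At
        arr[, , , dm[4] + seq_len(dm[4])] <- As
        arr
      } else At + As
    } else M <- At
    bn <- .bn_fwd(M, blk$bn, net$bn_state[[b]], train)
    if (train) net$bn_state[[b]] <- bn$state
    A <- bn$Y
    relu_mask <- A > 0
    A <- A * relu_mask
    if (train && cfg$dropout_p > 0) {
      drop_mask <- array((stats::runif(length(A)) >= cfg$dropout_p) /
                           (1 - cfg$dropout_p), dim(A))
      A <- A * drop_mask
    } else drop_mask <- NULL
    if (keep_cache) {
      cache$At <- At
      if (net$channel_mode == "spatial") cache$As <- As
      cache$bn <- bn$cache
      cache$relu_mask <- relu_mask
      cache$drop_mask <- drop_mask
      cache$out <- A
      caches[[b]] <- cache
    }
    H <- A
  }
  d <- dim(H)
  if (net$channel_mode == "independent") {
    M <- aperm(H, c(1, 4, 2, 3))
    dim(M) <- c(d[1] * d[4], d[2] * d[3])
    P <- matrix(rowMeans(M), d[1], d[4])
  } else {
    M <- aperm(H, c(1, 3, 4, 2))
    dim(M) <- c(d[1] * d[3] * d[4], d[2])
    P <- matrix(rowMeans(M), d[1], d[3] * d[4])
  }
  logits <- sweep(P %*% net$params$head$W, 2, net$params$head$b, "+")
  list(logits = logits, probs = .softmax(logits), P = P, H_dim = d,
       caches = caches, X_in = X, net = net)
}

# backward from d(logits); returns parameter gradients and dX at the input
.nn_backward <- function(fwd, dlogits, train = TRUE) {
  net <- fwd$net; cfg <- net$cfg
  d <- fwd$H_dim
  g <- list(blocks = vector("list", cfg$n_blocks),
            head = list(W = crossprod(fwd$P, dlogits),
                        b = colSums(dlogits)))
  dP <- dlogits %*% t(net$params$head$W)
  if (net$channel_mode == "independent") {
    dH <- array(0, d)
    per <- dP / (d[2] * d[3])
    for (f in seq_len(d[4])) dH[, , , f] <- per[, f]
  } else {
    dH <- array(0, d)
    dPa <- array(dP, c(d[1], d[3], d[4]))
    dH <- aperm(array(rep(dPa / d[2], d[2]),
                      c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  }
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- net$params$blocks[[b]]
    cache <- fwd$caches[[b]]
    dil <- cfg$dilations[min(b, length(cfg$dilations))]
    dA <- dH
    if (!is.null(cache$drop_mask)) dA <- dA * cache$drop_mask
    dA <- dA * cache$relu_mask
    if (train) {
      bb <- .bn_bwd_train(dA, cache$bn, blk$bn$gamma)
      dM <- array(bb$dX, dim(dA))
      gbn <- list(gamma = bb$dgamma, beta = bb$dbeta)
    } else {
      dM <- array(.bn_bwd_eval(dA, blk$bn$gamma,
                               net$bn_state[[b]]$rvar), dim(dA))
      gbn <- NULL
    }
    if (net$channel_mode == "spatial") {
      fo <- dim(cache$At)[4]
      if (cfg$merge == "concat") {
        dAt <- dM[, , , seq_len(fo), drop = FALSE]
        dAs <- dM[, , , fo + seq_len(fo), drop = FALSE]
      } else { dAt <- dM; dAs <- dM }
      bt <- .tconv_bwd(dAt, cache$X, blk$t$W, dil)
      bs <- .sconv_bwd(dAs, cache$X, blk$s$W)
      dH <- bt$dX + bs$dX
      g$blocks[[b]] <- list(t = list(W = bt$dW, b = bt$db),
                            s = list(W = bs$dW, b = bs$db), bn = gbn)
    } else {
      bt <- .tconv_bwd(dM, cache$X, blk$t$W, dil)
      dH <- bt$dX
      g$blocks[[b]] <- list(t = list(W = bt$dW, b = bt$db), bn = gbn)
    }
  }
  list(grads = g, dX = dH)
}

# cross-entropy loss and d(logits) for integer labels in 1..K
.ce_loss <- function(probs, y) {
  n <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(n), y)], 1e-12)
  -mean(log(p))
}

.ce_dlogits <- function(probs, y) {
  n <- nrow(probs)
  d <- probs
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  d / n
}

# ---- optimisation ------------------------------------------------------

.tree_zeros <- function(x) {
  if (is.numeric(x)) return(array(0, if (is.null(dim(x))) length(x)
                                  else dim(x)))
  if (is.list(x)) return(lapply(x, .tree_zeros))
  NULL
}

.adam_step <- function(params, grads, m, v, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, mm, vv) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, m = mm, v = vv))
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g ^ 2
      mhat <- mm / (1 - beta1 ^ t)
      vhat <- vv / (1 - beta2 ^ t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    } else if (is.list(p)) {
      out <- list(p = p, m = mm, v = vv)
      for (i in seq_along(p)) {
        if (is.null(p[[i]]) || is.null(g[[i]])) next
        r <- step(p[[i]], g[[i]], mm[[i]], vv[[i]])
        out$p[[i]] <- r$p; out$m[[i]] <- r$m; out$v[[i]] <- r$v
      }
      out
    } else list(p = p, m = mm, v = vv)
  }
  step(params, grads, m, v)
}

# ---- training loop -----------------------------------------------------

.nn_train <- function(net, X, y, epochs = 30L, batch_size = 32L, lr = 1e-3,
                      val_frac = 0.2, patience = 10L, verbose = FALSE) {
  N <- dim(X)[1]
  stopifnot(length(y) == N)
  # stratified validation split
  val_idx <- integer(0)
  if (val_frac > 0 && N >= 10L) {
    for (k in unique(y)) {
      idx <- which(y == k)
      n_val <- max(1L, floor(length(idx) * val_frac))
      if (length(idx) > n_val)
        val_idx <- c(val_idx, sample(idx, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  Xtr <- X[tr_idx, , , , drop = FALSE]; ytr <- y[tr_idx]
  has_val <- length(val_idx) > 0L
  if (has_val) { Xval <- X[val_idx, , , , drop = FALSE]; yval <- y[val_idx] }

  m <- .tree_zeros(net$params); v <- .tree_zeros(net$params)
  best <- list(loss = Inf, params = net$params, bn_state = net$bn_state,
               epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_acc = numeric(0))
  t_adam <- 0L; stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(ytr))
    tl <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      fwd <- .nn_forward(net, Xtr[bi, , , , drop = FALSE], train = TRUE,
                         keep_cache = TRUE)
      net$bn_state <- fwd$net$bn_state
      loss <- .ce_loss(fwd$probs, ytr[bi])
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      bwd <- .nn_backward(fwd, .ce_dlogits(fwd$probs, ytr[bi]), train = TRUE)
      t_adam <- t_adam + 1L
      upd <- .adam_step(net$params, bwd$grads, m, v, lr, t_adam)
      net$params <- upd$p; m <- upd$m; v <- upd$v
      tl <- tl + loss; nb <- nb + 1L
    }
    if (has_val) {
      fv <- .nn_forward(net, Xval, train = FALSE)
      vloss <- .ce_loss(fv$probs, yval)
      vacc <- mean(max.col(fv$probs) == yval)
    } else { vloss <- tl / nb; vacc <- NA_real_ }
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / nb,
                                 val_loss = vloss, val_acc = vacc))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                      ep, tl / nb, vloss, vacc))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = net$params,
                   bn_state = net$bn_state, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  net$params <- best$params
  net$bn_state <- best$bn_state
  net$log <- log
  net
}

.nn_predict <- function(net, X) {
  .nn_forward(net, X, train = FALSE)$probs
}

# |d logit_c / d input| for one or more samples
.nn_input_grad <- function(net, X, class_idx) {
  fwd <- .nn_forward(net, X, train = FALSE, keep_cache = TRUE)
  dlogits <- matrix(0, nrow(fwd$logits), ncol(fwd$logits))
  dlogits[, class_idx] <- 1
  bwd <- .nn_backward(fwd, dlogits, train = FALSE)
  dX <- bwd$dX
  if (net$channel_mode == "flatten") {
    d <- net$input_shape
    dX <- array(dX, c(dim(X)[1], d[1], d[2], d[3]))
  }
  dX
}
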