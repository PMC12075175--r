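#' Network decoder configuration
#'
#' Architecture and training hyper-parameters shared by the vanilla temporal
#' convolutional network (TCN) and the simultaneous spatio-temporal
#' convolutional network (STCN). Each STCN block runs two parallel branches
#' on its input -- a causal dilated convolution along time and a circular
#' convolution across the channel axis at each time step -- merges them,
#' then applies batch normalization, ReLU and dropout. The vanilla TCN is
#' the same stack with the spatial branch removed; its channel handling is
#' either \code{"flatten"} (channels folded into the feature axis, the
#' default) or \code{"independent"} (weights shared across channels and
#' channel-agnostic pooling, a deliberately spatially-blind variant). The
#' head is global temporal average pooling followed by a softmax layer.
#'
#' @param n_blocks number of convolutional blocks.
#' @param temporal_kernel causal kernel size along time.
#' @param dilations per-block dilation factors.
#' @param spatial_kernel channel-span of the spatial branch (odd; circular,
#'   matching the ring geometry of an armband).
#' @param filters feature maps per branch and block.
#' @param dropout_p dropout probability in \[0, 1).
#' @param merge \code{"concat"} or \code{"sum"} for the branch merge.
#' @param channel_mode vanilla-TCN channel handling (ignored by the STCN).
#' @param epochs,batch_size,lr,val_frac,patience training-loop settings
#'   (Adam, cross-entropy, early stopping on validation loss).
#' @return a list of class \code{stcn_config}.
#' @export
stcn_config <- function(n_blocks = 3L, temporal_kernel = 3L,
                        dilations = c(1L, 2L, 4L), spatial_kernel = 3L,
                        filters = 32L, dropout_p = 0.3,
                        merge = c("concat", "sum"),
                        channel_mode = c("flatten", "independent"),
                        epochs = 100L, batch_size = 32L, lr = 1e-3,
                        val_frac = 0.2, patience = 10L) {
  merge <- match.arg(merge)
  channel_mode <- match.arg(channel_mode)
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (any(dilations < 1)) stop("dilations must be positive")
  if (spatial_kernel %% 2L != 1L) stop("spatial_kernel must be odd")
  structure(list(n_blocks = as.integer(n_blocks),
                 temporal_kernel = as.integer(temporal_kernel),
                 dilations = as.integer(dilations),
                 spatial_kernel = as.integer(spatial_kernel),
                 filters = as.integer(filters), dropout_p = dropout_p,
                 merge = merge, channel_mode = channel_mode,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_frac = val_frac, patience = as.integer(patience)),
            class = "stcn_config")
}

#' Untrained decoder networks
#'
#' \code{build_stcn} instantiates the simultaneous spatio-temporal network;
#' \code{build_vanilla_tcn} the purely temporal baseline. Mostly useful for
#' inspecting architectures (\code{n_params}); \code{\link{fit_decoder}}
#' builds and trains in one call.
#'
#' @param cfg an \code{\link{stcn_config}}.
#' @param input_shape integer triple (time_steps, channels, features).
#' @param n_classes number of gesture classes.
#' @return an untrained network object (internal structure).
#' @export
build_stcn <- function(cfg = stcn_config(), input_shape, n_classes) {
  .nn_init(input_shape, n_classes, cfg, channel_mode = "spatial")
}

#' @rdname build_stcn
#' @export
build_vanilla_tcn <- function(cfg = stcn_config(), input_shape, n_classes) {
  .nn_init(input_shape, n_classes, cfg, channel_mode = cfg$channel_mode)
}

#' Number of trainable parameters of a network
#' @param net a network from \code{\link{build_stcn}} or
#'   \code{\link{build_vanilla_tcn}}, or a fitted \code{emg_decoder}.
#' @export
n_params <- function(net) {
  if (inherits(net, "emg_decoder")) net <- net$net
  .nn_n_params(net)
}

# ---- LDA ---------------------------------------------------------------

# pooled-covariance linear discriminant with shrinkage toward the scaled
# identity: Sigma_reg = (1 - lambda) Sigma + lambda * mean(diag(Sigma)) * I
.lda_fit <- function(X, y, lambda = 1e-3) {
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("LDA needs at least two classes")
  p <- ncol(X)
  means <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (k in classes) {
    Xc <- sweep(X[y == k, , drop = FALSE], 2, means[match(k, classes), ])
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X) - length(classes))
  priors <- as.numeric(table(factor(y, levels = classes))) / length(y)
  for (try_lambda in unique(c(lambda, 1e-2, 1e-1, 0.5))) {
    Sr <- (1 - try_lambda) * S +
      try_lambda * mean(diag(S)) * diag(p)
    ch <- tryCatch(chol(Sr), error = function(e) NULL)
    if (!is.null(ch)) {
      if (try_lambda > lambda)
        warning("singular pooled covariance; shrinkage raised to ",
                try_lambda)
      Sinv <- chol2inv(ch)
      # linear discriminant: w_k = Sigma^-1 mu_k, c_k = -mu_k' w_k / 2 + log pi_k
      W <- Sinv %*% t(means)
      const <- -colSums(t(means) * W) / 2 + log(priors)
      return(list(classes = classes, W = W, const = const,
                  means = means, lambda = try_lambda))
    }
  }
  stop("pooled covariance not invertible even with heavy shrinkage")
}

.lda_scores <- function(fit, X) {
  sweep(X %*% fit$W, 2, fit$const, "+")
}

.lda_probs <- function(fit, X) {
  .softmax(.lda_scores(fit, X))
}

# ---- unified fitting surface ------------------------------------------

#' Fit a gesture decoder
#'
#' The single model-fitting entry point. Input is a windowed feature tensor
#' (\code{\link{extract_feature_tensor}} output or a plain
#' \code{[N, time_steps, channels, features]} array) with one gesture label
#' per sample. Standardization statistics (per channel-feature z-score) are
#' computed on the training data and stored with the model.
#'
#' \describe{
#'   \item{lda}{shrinkage-regularized pooled-covariance linear discriminant
#'     on per-window feature vectors (channels x features, flattened); a
#'     sample is classified by majority vote over its \code{time_steps}
#'     windows.}
#'   \item{tcn}{vanilla temporal convolutional network.}
#'   \item{stcn}{simultaneous spatio-temporal convolutional network.}
#' }
#'
#' @param x an \code{emg_features} object or \code{[N,T,C,F]} array.
#' @param labels integer class labels (1-based), length N; taken from
#'   \code{x} when omitted.
#' @param kind decoder type.
#' @param config an \code{\link{stcn_config}} (networks) or a list with
#'   \code{lambda} (LDA shrinkage).
#' @param classes optional character vector of class names.
#' @param seed RNG seed; fixed seed gives bit-identical fits.
#' @param verbose print training progress.
#' @return object of class \code{emg_decoder} with \code{print},
#'   \code{summary} and \code{predict} methods.
#' @export
fit_decoder <- function(x, labels = NULL, kind = c("lda", "tcn", "stcn"),
                        config = NULL, classes = NULL, seed = 1L,
                        verbose = FALSE) {
  kind <- match.arg(kind)
  if (inherits(x, "emg_features")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(classes)) classes <- x$classes
    wlabels <- x$window_labels
    tensor <- x$tensor
  } else {
    tensor <- x
    wlabels <- NULL
  }
  stopifnot(length(dim(tensor)) == 4L, !is.null(labels))
  labels <- as.integer(labels)
  d <- dim(tensor)
  n_classes <- if (!is.null(classes)) length(classes) else max(labels)
  if (is.null(classes)) classes <- as.character(seq_len(n_classes))
  set.seed(seed)
  std <- standardize_features(tensor)
  stats <- attr(std, "standardization")

  if (kind == "lda") {
    lambda <- if (!is.null(config$lambda)) config$lambda else 1e-3
    # per-window training rows (row i + (t-1)*N = sample i, window t);
    # window labels when available, else the sample label repeated
    Xw <- matrix(std, d[1] * d[2], d[3] * d[4])
    yw <- if (!is.null(wlabels)) as.integer(wlabels)
          else rep(labels, times = d[2])
    fit <- .lda_fit(Xw, yw, lambda)
    out <- list(kind = "lda", fit = fit, standardization = stats,
                classes = classes, n_classes = n_classes,
                input_shape = d[2:4], log = NULL)
  } else {
    cfg <- if (is.null(config)) stcn_config() else config
    net <- if (kind == "stcn") build_stcn(cfg, d[2:4], n_classes)
           else build_vanilla_tcn(cfg, d[2:4], n_classes)
    net <- .nn_train(net, std, labels, epochs = cfg$epochs,
                     batch_size = cfg$batch_size, lr = cfg$lr,
                     val_frac = cfg$val_frac, patience = cfg$patience,
                     verbose = verbose)
    out <- list(kind = kind, net = net, standardization = stats,
                classes = classes, n_classes = n_classes,
                input_shape = d[2:4], log = net$log)
  }
  class(out) <- "emg_decoder"
  out
}

#' Predict gesture classes or probabilities
#'
#' @param object an \code{emg_decoder}.
#' @param newdata an \code{emg_features} object or \code{[N,T,C,F]} array.
#' @param type \code{"class"} (default) or \code{"prob"}.
#' @param ... unused.
#' @return integer class ids, or an \code{[N, classes]} probability matrix
#'   whose rows sum to 1.
#' @export
predict.emg_decoder <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  tensor <- if (inherits(newdata, "emg_features")) newdata$tensor else newdata
  if (length(dim(tensor)) == 3L)
    tensor <- array(tensor, c(1L, dim(tensor)))
  d <- dim(tensor)
  std <- standardize_features(tensor, stats = object$standardization)
  if (object$kind == "lda") {
    Xw <- matrix(std, d[1] * d[2], d[3] * d[4])
    pw <- .lda_probs(object$fit, Xw)   # window posteriors
    K <- object$n_classes
    probs <- matrix(0, d[1], K)
    votes <- matrix(0L, d[1], K)
    cls_w <- object$fit$classes[max.col(pw)]
    for (i in seq_len(d[1])) {
      rows <- seq.int(i, d[1] * d[2], by = d[1])
      probs[i, object$fit$classes] <- colMeans(pw[rows, , drop = FALSE])
      tb <- tabulate(cls_w[rows], nbins = K)
      votes[i, ] <- tb
    }
    cls <- integer(d[1])
    for (i in seq_len(d[1])) {
      top <- which(votes[i, ] == max(votes[i, ]))
      cls[i] <- if (length(top) == 1L) top
                else top[which.max(probs[i, top])]  # tie: mean posterior
    }
  } else {
    probs <- .nn_predict(object$net, std)
    cls <- max.col(probs)
  }
  if (type == "prob") probs else cls
}

#' @export
print.emg_decoder <- function(x, ...) {
  cat(sprintf("EMG gesture decoder (%s), %d classes: %s\n", x$kind,
              x$n_classes, paste(x$classes, collapse = ", ")))
  cat(sprintf("  input: %d time steps x %d channels x %d features\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3]))
  if (x$kind != "lda")
    cat(sprintf("  %d trainable parameters, trained %d epochs\n",
                n_params(x), max(x$log$epoch)))
  invisible(x)
}

#' @export
summary.emg_decoder <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    best <- which.min(object$log$val_loss)
    cat(sprintf("  best validation loss %.4f (epoch %d), accuracy %.3f\n",
                object$log$val_loss[best], object$log$epoch[best],
                object$log$val_acc[best]))
  } else {
    cat(sprintf("  LDA shrinkage lambda = %g\n", object$fit$lambda))
  }
  invisible(object)
}
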