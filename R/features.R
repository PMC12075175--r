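#' Spatio-temporal descriptor features
#'
#' The six per-window, per-channel time-domain descriptors used as decoder
#' input, in their fixed order:
#' \enumerate{
#'   \item integral square descriptor (signal power): \eqn{\sum x_i^2}
#'   \item ISD minus normalized root-square coefficient of the first
#'     difference: \eqn{\sum x_i^2 - \frac{1}{\theta}\sum DD_{x1,i}^2}
#'   \item the same with the second difference \eqn{DD_{x2}}
#'   \item mean logarithm kernel (geometric-mean magnitude):
#'     \eqn{|\exp(\frac{1}{n}\sum \log(|x_i| + \epsilon))|}
#'   \item mean value of the square root: \eqn{\frac{1}{n}\sum |x_i|^{1/2}}
#'   \item mean second difference (derivative of higher-order moments):
#'     \eqn{\frac{1}{n}\sum DD_{x2,i}}
#' }
#' \eqn{DD_{x1,i} = x_{i+1} - x_i} (length \eqn{n-1}) and
#' \eqn{DD_{x2,i} = x_{i+2} - 2x_{i+1} + x_i} (length \eqn{n-2}); divisors
#' stay \eqn{n}. Logs and square roots act on magnitudes, since raw EMG is
#' zero-mean and signed. \eqn{\theta} defaults to the window length \eqn{n}
#' (a normalization choice; it is exposed in \code{\link{feature_config}}).
#'
#' @param x numeric window.
#' @param order 1 or 2, the difference order for the RSC term.
#' @param theta normalization constant of the RSC term.
#' @param eps_log stabilizer added to \code{|x|} inside the log.
#' @return scalar feature value.
#' @name descriptor-features
NULL

#' @rdname descriptor-features
#' @export
feature_isd <- function(x) {
  if (!length(x)) stop("empty window")
  sum(x ^ 2)
}

#' @rdname descriptor-features
#' @export
feature_isd_minus_rsc <- function(x, order = 1, theta = length(x)) {
  if (length(x) < 3L) stop("window too short")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (theta <= 0) stop("theta must be positive")
  d <- diff(x, differences = order)
  sum(x ^ 2) - sum(d ^ 2) / theta
}

#' @rdname descriptor-features
#' @export
feature_mean_log_kernel <- function(x, eps_log = 1e-8) {
  if (!length(x)) stop("empty window")
  abs(exp(mean(log(abs(x) + eps_log))))
}

#' @rdname descriptor-features
#' @export
feature_mean_sqrt <- function(x) {
  if (!length(x)) stop("empty window")
  mean(sqrt(abs(x)))
}

#' @rdname descriptor-features
#' @export
feature_mean_dd2 <- function(x) {
  if (length(x) < 3L) stop("window too short")
  sum(diff(x, differences = 2)) / length(x)
}

#' Feature extraction configuration
#'
#' @param theta normalization constant for the RSC terms; \code{NULL} (the
#'   default) means the window length \code{n}.
#' @param eps_log stabilizer for the log kernel.
#' @return object of class \code{emg_feature_config}.
#' @export
feature_config <- function(theta = NULL, eps_log = 1e-8) {
  if (!is.null(theta) && theta <= 0) stop("theta must be positive")
  if (eps_log <= 0) stop("eps_log must be positive")
  structure(list(theta = theta, eps_log = eps_log),
            class = "emg_feature_config")
}

#' Feature names in tensor order
#' @export
feature_names <- function() {
  c("isd", "isd_rsc1", "isd_rsc2", "log_kernel", "mean_sqrt", "mean_dd2")
}

# all six features for every sliding window of one channel, via cumulative
# sums: each descriptor is a windowed sum of a pointwise transform.
.channel_features <- function(x, starts, L, theta, eps_log) {
  wsum <- function(v, k, off = 0L) {
    cs <- c(0, cumsum(v))
    cs[starts + off + k] - cs[starts + off]
  }
  d1 <- diff(x); d2 <- diff(x, differences = 2)
  isd <- wsum(x ^ 2, L)
  rsc1 <- wsum(d1 ^ 2, L - 1L)
  rsc2 <- wsum(d2 ^ 2, L - 2L)
  cbind(isd,
        isd - rsc1 / theta,
        isd - rsc2 / theta,
        exp(wsum(log(abs(x) + eps_log), L) / L),
        wsum(sqrt(abs(x)), L) / L,
        wsum(d2, L - 2L) / L)
}

# majority label of each window, for piecewise-constant label tracks
.window_labels <- function(labels, starts, L) {
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(k) {
    cs <- c(0, cumsum(labels == k))
    cs[starts + L] - cs[starts]
  }, numeric(length(starts)))
  counts <- matrix(counts, nrow = length(starts))
  classes[max.col(counts, ties.method = "first")]
}

#' Windowed feature tensor for decoding
#'
#' Computes the six descriptors for every overlapping window of every
#' channel, then tiles consecutive windows into non-overlapping model
#' samples of \code{time_steps} windows each: the decoder input tensor
#' \code{[samples, time_steps, channels, features]}. A sample's label is the
#' majority raw-sample label of its span; samples whose span touches two
#' different movement gestures are dropped. Each sample also carries the
#' index of the movement trial it (mostly) overlaps, so cross-validation can
#' keep whole trials in one fold.
#'
#' @param rec a (filtered) \code{\link{emg_recording}} with labels.
#' @param wspec an \code{\link{emg_window_spec}}.
#' @param fcfg an \code{\link{feature_config}}.
#' @param time_steps windows per model sample (60 by default, the model
#'   input length).
#' @return object of class \code{emg_features}: fields \code{tensor}
#'   (\code{[N, time_steps, channels, 6]} array), \code{labels} (length N),
#'   \code{window_labels} (\code{[N, time_steps]}), \code{trial} (length N),
#'   \code{classes}, \code{feature_names}.
#' @export
extract_feature_tensor <- function(rec, wspec = window_spec(fs = rec$fs),
                                   fcfg = feature_config(), time_steps = 60L) {
  stopifnot(inherits(rec, "emg_recording"))
  windows <- segment_windows(nrow(rec$data), wspec)
  L <- wspec$length_samples
  W <- nrow(windows)
  if (W < time_steps)
    stop("recording too short for one model sample of ", time_steps,
         " windows")
  theta <- if (is.null(fcfg$theta)) L else fcfg$theta
  C <- ncol(rec$data)
  n_seq <- W %/% time_steps
  used_w <- n_seq * time_steps
  feats <- array(NA_real_, c(used_w, C, 6L))
  starts <- windows$start[seq_len(used_w)]
  for (ch in seq_len(C))
    feats[, ch, ] <- .channel_features(rec$data[, ch], starts, L,
                                       theta, fcfg$eps_log)
  wlab <- .window_labels(rec$labels, starts, L)

  rest_id <- rec$meta$rest_id
  if (is.null(rest_id)) rest_id <- max(rec$labels)
  # movement-trial index per raw sample: nth run of non-rest labels;
  # rest samples inherit the preceding trial (0 before the first)
  mv <- rec$labels != rest_id
  run_start <- mv & !c(FALSE, mv[-length(mv)])
  trial_of_sample <- cumsum(run_start)

  seq_id <- rep(seq_len(n_seq), each = time_steps)
  span_start <- starts[seq(1L, used_w, by = time_steps)]
  span_end <- starts[seq(time_steps, used_w, by = time_steps)] + L - 1L

  labels <- integer(n_seq); trial <- integer(n_seq); keep <- logical(n_seq)
  for (i in seq_len(n_seq)) {
    span <- span_start[i]:span_end[i]
    lab <- rec$labels[span]
    tb <- tabulate(lab, nbins = max(rec$labels))
    labels[i] <- which.max(tb)
    gestures_present <- setdiff(unique(lab), rest_id)
    keep[i] <- length(gestures_present) <= 1L
    tt <- trial_of_sample[span]
    trial[i] <- as.integer(names(which.max(table(tt))))
  }

  tensor <- array(NA_real_, c(n_seq, time_steps, C, 6L))
  for (i in seq_len(n_seq))
    tensor[i, , , ] <- feats[seq_id == i, , , drop = FALSE]
  wl <- matrix(wlab, nrow = n_seq, byrow = TRUE)

  classes <- rec$meta$gesture_names
  if (is.null(classes)) classes <- as.character(sort(unique(rec$labels)))
  out <- list(tensor = tensor[keep, , , , drop = FALSE],
              labels = labels[keep],
              window_labels = wl[keep, , drop = FALSE],
              trial = trial[keep],
              classes = classes,
              feature_names = feature_names(),
              time_steps = as.integer(time_steps),
              window_spec = wspec)
  class(out) <- "emg_features"
  out
}

#' @export
print.emg_features <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "EMG feature tensor: %d samples x %d time steps x %d channels x %d features\n",
    d[1], d[2], d[3], d[4]))
  cat("  labels:", paste(sprintf("%s:%d", names(table(x$labels)),
                                 table(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Z-score standardization of a feature tensor
#'
#' Per channel-feature pair, using statistics from the given tensor (the
#' training split) or previously computed ones. Constant features get unit
#' scale to avoid division by zero.
#'
#' @param wf an \code{emg_features} object or a \code{[N,T,C,F]} array.
#' @param stats optional list with \code{mean} and \code{sd} matrices
#'   \code{[C, F]} from a training split.
#' @return the input with standardized tensor; the statistics used are
#'   attached as attribute \code{"standardization"}.
#' @export
standardize_features <- function(wf, stats = NULL) {
  tensor <- if (inherits(wf, "emg_features")) wf$tensor else wf
  d <- dim(tensor)
  if (is.null(stats)) {
    m <- apply(tensor, c(3, 4), mean)
    s <- apply(tensor, c(3, 4), stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    stats <- list(mean = m, sd = s)
  }
  big_m <- aperm(array(stats$mean, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  big_s <- aperm(array(stats$sd, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  tensor <- (tensor - big_m) / big_s
  if (inherits(wf, "emg_features")) {
    wf$tensor <- tensor
    attr(wf, "standardization") <- stats
    wf
  } else {
    attr(tensor, "standardization") <- stats
    tensor
  }
}
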