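#' Armband recording protocol
#'
#' Describes one synthetic recording session of a multichannel EMG armband:
#' how many gesture classes (the last class is always rest), how often each is
#' repeated, the movement/relaxation timing, the sampling rate, and the
#' electrode geometry (nodes around the forearm, channels per node).
#'
#' Defaults emulate a 21-channel medium-density armband session: 7 sensor
#' nodes of 3 channels each, 1,067 Hz sampling, six gesture classes
#' (power, lateral pinch, tripod, pointer, open, rest), 10 repetitions per
#' gesture, 6 s movement followed by 6 s rest per trial.
#'
#' @param n_gestures number of gesture classes including rest (last class).
#' @param reps_per_gesture repetitions of each gesture.
#' @param move_s,rest_s movement and relaxation duration per trial, seconds.
#' @param fs sampling rate in Hz; must exceed 700 Hz so that a 30--350 Hz
#'   band-pass is feasible.
#' @param n_nodes number of sensor nodes on the band.
#' @param channels_per_node channels per node (middle position is
#'   \code{ceiling(channels_per_node / 2)}).
#' @param seed integer seed controlling trial order and signal synthesis.
#' @return an object of class \code{emg_protocol}.
#' @export
emg_protocol <- function(n_gestures = 6L, reps_per_gesture = 10L,
                         move_s = 6, rest_s = 6, fs = 1067,
                         n_nodes = 7L, channels_per_node = 3L, seed = 1L) {
  n_gestures <- as.integer(n_gestures)
  reps_per_gesture <- as.integer(reps_per_gesture)
  n_nodes <- as.integer(n_nodes)
  channels_per_node <- as.integer(channels_per_node)
  if (n_gestures < 2L) stop("need at least one movement class plus rest")
  if (reps_per_gesture < 1L) stop("reps_per_gesture must be >= 1")
  if (!is.finite(move_s) || move_s <= 0) stop("move_s must be positive")
  if (!is.finite(rest_s) || rest_s <= 0) stop("rest_s must be positive")
  if (!is.finite(fs) || fs <= 700) stop("fs must exceed 700 Hz (2 x 350 Hz)")
  if (n_nodes < 1L || channels_per_node < 1L)
    stop("channel count must be positive")
  gestures <- if (n_gestures == 6L) {
    c("power", "lateral_pinch", "tripod", "pointer", "open", "rest")
  } else {
    c(paste0("gesture", seq_len(n_gestures - 1L)), "rest")
  }
  structure(list(
    n_gestures = n_gestures, reps_per_gesture = reps_per_gesture,
    move_s = move_s, rest_s = rest_s, fs = fs,
    n_nodes = n_nodes, channels_per_node = channels_per_node,
    n_channels = n_nodes * channels_per_node,
    gesture_names = gestures, rest_id = n_gestures,
    seed = as.integer(seed)
  ), class = "emg_protocol")
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat("EMG session protocol\n")
  cat(sprintf("  %d classes (%s), %d reps each\n", x$n_gestures,
              paste(x$gesture_names, collapse = ", "), x$reps_per_gesture))
  cat(sprintf("  %g s move + %g s rest per trial, fs = %g Hz\n",
              x$move_s, x$rest_s, x$fs))
  cat(sprintf("  %d nodes x %d channels = %d channels\n",
              x$n_nodes, x$channels_per_node, x$n_channels))
  invisible(x)
}

#' Gesture-specific spatial activation model
#'
#' Maps each gesture class to a per-channel activation gain in \[0, 1\]. The
#' gain scales the contraction amplitude of the band-limited carrier on that
#' channel, so the activation matrix is the spatial ground truth that the
#' decoders and saliency maps are later judged against. The rest class always
#' has zero gain everywhere.
#'
#' The default activation pattern is built so that two gesture pairs
#' (power/lateral pinch and tripod/pointer) share identical gains on the
#' middle channel of every node and differ only on the side channels. Under
#' the low-density view (middle channels only) those pairs become
#' indistinguishable in expectation, emulating the physiological premise that
#' extra electrodes over adjacent musculature carry real information.
#'
#' @param protocol an \code{\link{emg_protocol}}.
#' @param activation optional gesture-by-channel gain matrix
#'   (\code{n_gestures} rows); the last (rest) row must be all zero.
#' @param carrier_band Hz pair: band of the synthetic EMG carrier.
#' @param noise_floor_sd standard deviation of the additive baseline noise.
#' @param snr_target_db per-channel SNR (dB, in the on/off variance-ratio
#'   sense \code{10*log10(var_on/var_off - 1)}) realised by a channel with
#'   gain 1.
#' @param node_correlation correlation between carriers of channels in the
#'   same node.
#' @param ramp_s raised-cosine onset/offset ramp duration, seconds; 0 gives a
#'   square contraction envelope.
#' @return an object of class \code{emg_spatial_model}.
#' @export
emg_spatial_model <- function(protocol, activation = NULL,
                              carrier_band = c(30, 350),
                              noise_floor_sd = 1,
                              snr_target_db = 9.54,
                              node_correlation = 0.6,
                              ramp_s = 0.1) {
  stopifnot(inherits(protocol, "emg_protocol"))
  if (is.null(activation)) activation <- default_activation(protocol)
  activation <- as.matrix(activation)
  if (nrow(activation) != protocol$n_gestures ||
      ncol(activation) != protocol$n_channels)
    stop("activation must be n_gestures x n_channels")
  if (any(!is.finite(activation)) || any(activation < 0))
    stop("activation gains must be finite and non-negative")
  if (any(activation[protocol$rest_id, ] != 0))
    stop("rest class must have all-zero activation")
  mov <- activation[-protocol$rest_id, , drop = FALSE]
  if (any(apply(mov, 1, max) <= 0))
    warning("movement class(es) with all-zero activation: ",
            "their trials will be pure baseline noise")
  if (carrier_band[1] <= 0 || carrier_band[2] <= carrier_band[1] ||
      carrier_band[2] >= protocol$fs / 2)
    stop("carrier_band infeasible for the protocol sampling rate")
  if (noise_floor_sd <= 0) stop("noise_floor_sd must be positive")
  if (node_correlation < 0 || node_correlation >= 1)
    stop("node_correlation must be in [0, 1)")
  structure(list(
    activation = activation, carrier_band = carrier_band,
    noise_floor_sd = noise_floor_sd, snr_target_db = snr_target_db,
    node_correlation = node_correlation, ramp_s = ramp_s
  ), class = "emg_spatial_model")
}

#' Default gesture-by-channel activation gains
#'
#' Node-level gain profiles crossed with within-node side/middle/side
#' profiles; see \code{\link{emg_spatial_model}} for the rationale.
#'
#' @param protocol an \code{\link{emg_protocol}}.
#' @return gain matrix \code{n_gestures x n_channels}.
#' @export
default_activation <- function(protocol) {
  G <- protocol$n_gestures
  J <- protocol$n_nodes
  P <- protocol$channels_per_node
  act <- matrix(0, G, protocol$n_channels)
  # node gain templates, resampled to J nodes
  resamp <- function(v) stats::approx(seq_along(v), v, n = J)$y
  ng1 <- resamp(c(1, 0.9, 0.6, 0.3, 0.05, 0.05, 0.2))
  ng2 <- resamp(c(0.05, 0.3, 0.8, 1, 0.8, 0.3, 0.05))
  ng3 <- resamp(c(0.5, 0.2, 0.1, 0.2, 0.5, 1, 0.9))
  # within-node profiles (left, middle, right for P = 3)
  prof <- function(l, m, r) {
    if (P == 1L) return(m)
    stats::approx(c(1, (1 + P) / 2, P), c(l, m, r), n = P)$y
  }
  tpl <- list(
    list(ng1, prof(0.9, 1, 0.3)),   # power
    list(ng1, prof(0.3, 1, 0.9)),   # lateral pinch: same middles, sides swapped
    list(ng2, prof(1, 0.8, 0.2)),   # tripod
    list(ng2, prof(0.2, 0.8, 1)),   # pointer: same middles, sides swapped
    list(ng3, prof(0.7, 1, 0.7))    # open
  )
  for (g in seq_len(G - 1L)) {
    t <- tpl[[(g - 1L) %% length(tpl) + 1L]]
    act[g, ] <- as.vector(outer(t[[2]], t[[1]]))  # channel = (node-1)*P + pos
  }
  act
}

#' Trial schedule for a protocol
#'
#' Block-randomized trial order: each block holds every gesture class once in
#' a seed-determined permutation, repeated \code{reps_per_gesture} times.
#' Every trial occupies \code{move_s + rest_s} seconds; the scheduled interval
#' covers the movement segment only (1-based, inclusive sample indices).
#'
#' @param protocol an \code{\link{emg_protocol}}.
#' @return data frame with columns \code{gesture}, \code{block}, \code{start},
#'   \code{end}; one row per trial, \code{end - start + 1 ==
#'   round(move_s * fs)}.
#' @export
generate_trial_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "emg_protocol"))
  set.seed(protocol$seed)
  move_len <- round(protocol$move_s * protocol$fs)
  rest_len <- round(protocol$rest_s * protocol$fs)
  order <- unlist(lapply(seq_len(protocol$reps_per_gesture),
                         function(b) sample.int(protocol$n_gestures)))
  n_trials <- length(order)
  start <- (seq_len(n_trials) - 1L) * (move_len + rest_len) + 1L
  data.frame(
    gesture = order,
    block = rep(seq_len(protocol$reps_per_gesture),
                each = protocol$n_gestures),
    start = start,
    end = start + move_len - 1L
  )
}

# band-pass filtered white noise, normalized to unit sd.
# Order-6 Butterworth, applied in one causal pass, keeps >95% of the
# carrier power strictly inside the band with margin.
.carrier_filter <- function(band, fs) {
  signal::butter(6, band / (fs / 2), type = "pass")
}

# one causal IIR pass without the ts-class overhead of signal::filter
.iir_pass <- function(x, flt) {
  b <- flt$b; a <- flt$a
  nb <- length(b)
  xp <- c(numeric(nb - 1), x)          # zero initial conditions
  xf <- stats::filter(xp, b, method = "convolution", sides = 1)
  xf <- xf[nb:length(xp)]
  as.numeric(stats::filter(xf, -a[-1], method = "recursive"))
}

#' Simulate one labeled armband session
#'
#' Per channel the signal is \code{carrier * (amplitude * envelope) +
#' baseline noise}: the carrier is band-limited Gaussian noise (correlated
#' between channels of one node), the envelope is a raised-cosine-ramped gate
#' over the scheduled movement intervals, and the amplitude realises the
#' spatial model's per-channel SNR target. The label track marks every sample
#' with its gesture id (the rest id between trials and during rest-class
#' trials).
#'
#' @param protocol an \code{\link{emg_protocol}}.
#' @param spatial an \code{\link{emg_spatial_model}}; default built from the
#'   protocol.
#' @param subject,session identifiers stored in the recording metadata.
#' @return an \code{\link{emg_recording}}.
#' @export
generate_session <- function(protocol, spatial = emg_spatial_model(protocol),
                             subject = "S01", session = "synthetic") {
  stopifnot(inherits(protocol, "emg_protocol"),
            inherits(spatial, "emg_spatial_model"))
  sched <- generate_trial_schedule(protocol)
  move_len <- round(protocol$move_s * protocol$fs)
  rest_len <- round(protocol$rest_s * protocol$fs)
  n <- nrow(sched) * (move_len + rest_len)
  C <- protocol$n_channels
  P <- protocol$channels_per_node
  set.seed(protocol$seed + 1L)

  # node-correlated carriers; one second of warm-up is synthesized and
  # dropped so no channel carries the filter startup transient
  bf <- .carrier_filter(spatial$carrier_band, protocol$fs)
  rho <- spatial$node_correlation
  warm <- round(protocol$fs)
  carriers <- matrix(0, n, C)
  for (j in seq_len(protocol$n_nodes)) {
    shared <- stats::rnorm(n + warm)
    for (p in seq_len(P)) {
      ch <- (j - 1L) * P + p
      raw <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n + warm)
      flt <- .iir_pass(raw, bf)[(warm + 1L):(warm + n)]
      carriers[, ch] <- flt / stats::sd(flt)
    }
  }

  # contraction envelope per channel, from the schedule and activation gains
  ramp_len <- round(spatial$ramp_s * protocol$fs)
  gate <- rep(1, move_len)
  if (ramp_len > 0) {
    r <- (1 - cos(pi * seq_len(ramp_len) / ramp_len)) / 2
    gate[seq_len(ramp_len)] <- r
    gate[move_len + 1L - seq_len(ramp_len)] <- r
  }
  env <- matrix(0, n, C)
  labels <- rep.int(protocol$rest_id, n)
  for (t in seq_len(nrow(sched))) {
    idx <- sched$start[t]:sched$end[t]
    labels[idx] <- sched$gesture[t]
    g <- sched$gesture[t]
    gains <- spatial$activation[g, ]
    on <- which(gains > 0)
    if (length(on)) env[idx, on] <- env[idx, on, drop = FALSE] +
        outer(gate, gains[on])
  }

  amp0 <- spatial$noise_floor_sd * sqrt(10 ^ (spatial$snr_target_db / 10))
  noise <- matrix(stats::rnorm(n * C, sd = spatial$noise_floor_sd), n, C)
  data <- carriers * (amp0 * env) + noise

  emg_recording(data, fs = protocol$fs, labels = labels,
                channel_map = data.frame(
                  channel = seq_len(C),
                  node = rep(seq_len(protocol$n_nodes), each = P),
                  pos = rep(seq_len(P), protocol$n_nodes)),
                meta = list(subject = subject, session = session,
                            seed = protocol$seed,
                            gesture_names = protocol$gesture_names,
                            rest_id = protocol$rest_id))
}
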