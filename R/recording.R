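#' Labeled multichannel EMG recording
#'
#' The session container used throughout the package: a samples-by-channels
#' signal matrix, the sampling rate, a per-sample integer gesture label track,
#' and a channel map locating every channel on the armband (node index and
#' within-node position).
#'
#' @param data numeric matrix, samples x channels.
#' @param fs sampling rate, Hz.
#' @param labels integer vector, one gesture id per sample.
#' @param channel_map data frame with columns \code{channel}, \code{node},
#'   \code{pos} covering every channel exactly once; defaulted to nodes of 3
#'   when omitted and the channel count allows it.
#' @param meta named list of free-form session metadata (subject, session,
#'   gesture names, ...).
#' @return object of class \code{emg_recording}.
#' @export
emg_recording <- function(data, fs, labels, channel_map = NULL, meta = list()) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  storage.mode(data) <- "double"
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  labels <- as.integer(labels)
  if (length(labels) != nrow(data))
    stop("labels length must equal the number of samples")
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite with no NA")
  C <- ncol(data)
  if (is.null(channel_map)) {
    per <- if (C %% 3L == 0L) 3L else 1L
    channel_map <- data.frame(channel = seq_len(C),
                              node = rep(seq_len(C %/% per), each = per),
                              pos = rep(seq_len(per), C %/% per))
  }
  channel_map <- as.data.frame(channel_map)
  if (!all(c("channel", "node", "pos") %in% names(channel_map)))
    stop("channel_map needs columns channel, node, pos")
  if (nrow(channel_map) != C || anyDuplicated(channel_map$channel) ||
      !setequal(channel_map$channel, seq_len(C)))
    stop("channel_map must cover all channels uniquely")
  channel_map <- channel_map[order(channel_map$channel),
                             c("channel", "node", "pos")]
  rownames(channel_map) <- NULL
  structure(list(data = data, fs = fs, labels = labels,
                 channel_map = channel_map, meta = meta),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
      "\n")
  if (!is.null(x$meta$subject))
    cat("  subject:", x$meta$subject, " session:", x$meta$session, "\n")
  invisible(x)
}

#' @export
summary.emg_recording <- function(object, ...) {
  v <- apply(object$data, 2, stats::var)
  out <- list(n_samples = nrow(object$data), n_channels = ncol(object$data),
              fs = object$fs, duration_s = nrow(object$data) / object$fs,
              channel_variance = v, label_counts = table(object$labels))
  class(out) <- "summary.emg_recording"
  out
}

#' @export
print.summary.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d samples x %d channels at %g Hz (%.1f s)\n",
              x$n_samples, x$n_channels, x$fs, x$duration_s))
  cat("  channel variance range:",
      sprintf("%.3g .. %.3g", min(x$channel_variance),
              max(x$channel_variance)), "\n")
  print(x$label_counts)
  invisible(x)
}

#' Reduce a recording to a density configuration
#'
#' \code{"medium"} keeps every channel; \code{"low"} keeps one channel per
#' node -- the within-node middle position (position 2 of 1..3 on the default
#' geometry), emulating a conventional single-channel-per-site montage.
#'
#' @param rec an \code{\link{emg_recording}}.
#' @param mode \code{"medium"} or \code{"low"}.
#' @return an \code{\link{emg_recording}} with the selected channels.
#' @export
select_density <- function(rec, mode = c("medium", "low")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "emg_recording"))
  if (mode == "medium") return(rec)
  cm <- rec$channel_map
  # middle position of 1..P: 2 for P = 3, 1 for P = 1; also maps the already
  # reduced montage (all pos == 2) onto itself, making low-density idempotent
  middle <- ceiling((max(cm$pos) + 1) / 2)
  keep <- integer(0)
  for (nd in sort(unique(cm$node))) {
    sub <- cm[cm$node == nd, ]
    hit <- sub$channel[sub$pos == middle]
    if (length(hit) != 1L)
      stop(sprintf("node %d lacks a unique middle channel (pos %d)",
                   nd, middle))
    keep <- c(keep, hit)
  }
  keep <- sort(keep)
  emg_recording(rec$data[, keep, drop = FALSE], fs = rec$fs,
                labels = rec$labels,
                channel_map = data.frame(channel = seq_along(keep),
                                         node = cm$node[keep],
                                         pos = cm$pos[keep]),
                meta = c(rec$meta, list(density = "low")))
}
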