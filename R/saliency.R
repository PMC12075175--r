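#' Gradient saliency for one sample
#'
#' Computes \eqn{|\partial S_c / \partial I|}, the absolute gradient of the
#' class score (pre-softmax logit; softmax saturation would otherwise
#' flatten the maps) with respect to the standardized input tensor,
#' element-wise over \code{[time_steps, channels, features]}. Only the
#' differentiable network decoders support this; the linear discriminant
#' raises an error.
#'
#' @param decoder a fitted \code{emg_decoder} of kind \code{tcn} or
#'   \code{stcn}.
#' @param sample one input sample: \code{[T, C, F]} array (or
#'   \code{[1, T, C, F]}).
#' @param gesture class index (1-based) or class name.
#' @return numeric array \code{[T, C, F]} of non-negative scores.
#' @export
saliency_single <- function(decoder, sample, gesture) {
  stopifnot(inherits(decoder, "emg_decoder"))
  if (decoder$kind == "lda")
    stop("saliency requires a differentiable decoder (tcn/stcn), not lda")
  if (is.character(gesture)) {
    gesture <- match(gesture, decoder$classes)
    if (is.na(gesture)) stop("unknown gesture name")
  }
  if (gesture < 1L || gesture > decoder$n_classes)
    stop("gesture index out of range")
  if (length(dim(sample)) == 3L) sample <- array(sample, c(1L, dim(sample)))
  std <- standardize_features(sample, stats = decoder$standardization)
  g <- .nn_input_grad(decoder$net, std, gesture)
  array(abs(g[1, , , ]), dim(sample)[2:4])
}

#' Average a raw saliency array over the feature axis
#'
#' The channel-level view of the maps: \code{[T, C, F]} scores are averaged
#' along the feature dimension, yielding a \code{[time_steps, channels]}
#' map.
#'
#' @param raw \code{[T, C, F]} array from \code{\link{saliency_single}}.
#' @param gesture optional gesture id/name carried in the result.
#' @return object of class \code{emg_saliency}: matrix \code{scores}
#'   \code{[T, C]} plus \code{gesture} and \code{aggregation} fields.
#' @export
average_features <- function(raw, gesture = NA) {
  stopifnot(length(dim(raw)) == 3L, all(is.finite(raw)))
  scores <- apply(raw, c(1, 2), mean)
  structure(list(scores = scores, gesture = gesture,
                 aggregation = "single-sample"),
            class = "emg_saliency")
}

#' Aggregate saliency maps
#'
#' Element-wise mean of homogeneous maps, across samples or subjects.
#'
#' @param maps list of \code{emg_saliency} objects (or \code{[T, C]}
#'   matrices) of identical shape.
#' @param level \code{"samples"} or \code{"subjects"}; recorded in the
#'   result.
#' @return an \code{emg_saliency}.
#' @export
aggregate_maps <- function(maps, level = c("samples", "subjects")) {
  level <- match.arg(level)
  mats <- lapply(maps, function(m)
    if (inherits(m, "emg_saliency")) m$scores else m)
  d0 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d0), TRUE)))
    stop("saliency maps have mismatching shapes")
  scores <- Reduce(`+`, mats) / length(mats)
  gesture <- if (inherits(maps[[1]], "emg_saliency")) maps[[1]]$gesture
             else NA
  structure(list(scores = scores, gesture = gesture,
                 aggregation = paste0("mean-over-", level)),
            class = "emg_saliency")
}

#' Per-gesture saliency maps from a fitted network
#'
#' Convenience wrapper: for each requested gesture, computes single-sample
#' maps on the correctly-classified samples of that gesture, averages the
#' feature axis, and aggregates across samples.
#'
#' @param decoder fitted \code{tcn}/\code{stcn} decoder.
#' @param x an \code{emg_features} object or \code{[N,T,C,F]} array.
#' @param labels sample labels (taken from \code{x} when omitted).
#' @param gestures class indices to map; defaults to all movement classes
#'   present.
#' @param max_samples cap on samples per gesture (keeps runtime bounded).
#' @return named list of \code{emg_saliency} maps.
#' @export
saliency_maps <- function(decoder, x, labels = NULL, gestures = NULL,
                          max_samples = 20L) {
  tensor <- if (inherits(x, "emg_features")) x$tensor else x
  if (is.null(labels) && inherits(x, "emg_features")) labels <- x$labels
  stopifnot(!is.null(labels))
  preds <- predict(decoder, tensor)
  if (is.null(gestures)) gestures <- sort(unique(labels))
  out <- list()
  for (g in gestures) {
    idx <- which(labels == g & preds == g)
    if (!length(idx)) idx <- which(labels == g)  # fall back: misclassified
    idx <- idx[seq_len(min(length(idx), max_samples))]
    maps <- lapply(idx, function(i)
      average_features(
        saliency_single(decoder, tensor[i, , , , drop = TRUE], g),
        gesture = g))
    out[[decoder$classes[g]]] <- aggregate_maps(maps, "samples")
  }
  out
}

#' @export
print.emg_saliency <- function(x, ...) {
  cat(sprintf("Saliency map [%d time steps x %d channels], %s",
              nrow(x$scores), ncol(x$scores), x$aggregation))
  if (!is.na(x$gesture)) cat(", gesture", x$gesture)
  cat("\n  top channels:",
      paste(order(colMeans(x$scores), decreasing = TRUE)[1:min(3, ncol(x$scores))],
            collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap of a saliency map
#'
#' @param x an \code{emg_saliency}.
#' @param ... passed to \code{image}.
#' @export
plot.emg_saliency <- function(x, ...) {
  graphics::image(seq_len(nrow(x$scores)), seq_len(ncol(x$scores)),
                  x$scores, xlab = "time step", ylab = "channel",
                  main = paste("Saliency", x$aggregation), ...)
  invisible(x)
}

#' Write a saliency map to CSV
#'
#' Rows are time steps, columns channels.
#'
#' @param map an \code{emg_saliency}.
#' @param path output CSV path.
#' @export
write_saliency <- function(map, path) {
  m <- map$scores
  colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
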