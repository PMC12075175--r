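# Packaged study designs: the synthetic counterparts of the armband
# evaluation, at a scale a single CPU handles in minutes. Both the test
# suite and the reproduction script call these, so the designs live in one
# place.

#' Rotation-structured activation patterns
#'
#' Builds a gesture-by-channel gain matrix in which every movement class is
#' the same spatial bump rotated around the band, so class identity is
#' carried purely by the spatial arrangement of activity: each movement
#' class has identical per-channel gain multisets and identical temporal
#' statistics, and only the location of the bump differs.
#'
#' @param protocol an \code{\link{emg_protocol}}.
#' @param bump_width channels covered by the activation bump.
#' @return gain matrix \code{n_gestures x n_channels}.
#' @export
rotation_activation <- function(protocol, bump_width = 5L) {
  C <- protocol$n_channels
  G <- protocol$n_gestures
  base <- numeric(C)
  base[seq_len(bump_width)] <-
    (1 - cos(2 * pi * seq_len(bump_width) / (bump_width + 1))) / 2
  act <- matrix(0, G, C)
  shift <- floor(C / (G - 1L))
  for (g in seq_len(G - 1L)) {
    off <- (g - 1L) * shift
    act[g, ] <- base[((seq_len(C) - 1L - off) %% C) + 1L]
  }
  act
}

#' Medium- vs low-density decoding comparison on a synthetic cohort
#'
#' The density study at desk scale: a cohort of synthetic subjects, each
#' cross-validated with the LDA decoder under the full 21-channel montage
#' and the 7-middle-channel montage, followed by a paired Wilcoxon
#' signed-rank test. The default activation patterns make two gesture pairs
#' identical on the middle channels, so the low-density view loses real
#' information.
#'
#' @param n_subjects cohort size.
#' @param reps repetitions per gesture.
#' @param move_s,rest_s trial timing, seconds.
#' @param time_steps windows per model sample.
#' @param k cross-validation folds.
#' @param seed base seed.
#' @return list: \code{acc} (accuracy table), \code{comparison}
#'   (\code{\link{compare_conditions}} result).
#' @export
density_experiment <- function(n_subjects = 10L, reps = 5L, move_s = 3,
                               rest_s = 2, time_steps = 30L, k = 3L,
                               seed = 1L) {
  protocol <- emg_protocol(reps_per_gesture = reps, move_s = move_s,
                           rest_s = rest_s, seed = seed)
  sessions <- simulate_subjects(n_subjects, protocol)
  acc <- evaluate_sessions(sessions, kinds = "lda",
                           densities = c("medium", "low"), k = k,
                           time_steps = time_steps, seed = seed)
  comparison <- suppressWarnings(compare_conditions(acc))
  list(acc = acc, comparison = comparison)
}

#' Spatio-temporal vs purely temporal decoding on spatially-coded gestures
#'
#' Trains the spatio-temporal network and the vanilla TCN on sessions whose
#' class identity is purely spatial (\code{\link{rotation_activation}}),
#' holding one repetition block out for testing, over several seeds. The
#' vanilla baseline runs in its per-channel-independent mode -- the variant
#' that is spatially blind by construction -- so the comparison isolates the
#' value of spatial feature learning (the flattened variant can read
#' channel identity from its input layout and would not).
#'
#' @param n_seeds paired replicates.
#' @param reps repetitions per gesture (last block is the test set).
#' @param move_s,rest_s trial timing.
#' @param time_steps windows per model sample.
#' @param epochs training epochs per model.
#' @param seed base seed.
#' @return list: \code{acc} (data frame seed x decoder accuracy),
#'   \code{p_value} (one-sided paired Wilcoxon, stcn > tcn).
#' @export
spatial_advantage_experiment <- function(n_seeds = 10L, reps = 3L,
                                         move_s = 2, rest_s = 1,
                                         time_steps = 10L, epochs = 20L,
                                         seed = 1L) {
  cfg <- stcn_config(n_blocks = 2L, dilations = c(1L, 2L), filters = 8L,
                     dropout_p = 0.1, epochs = epochs, patience = epochs,
                     lr = 1e-2, channel_mode = "independent")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    protocol <- emg_protocol(reps_per_gesture = reps, move_s = move_s,
                             rest_s = rest_s, seed = seed + 131L * s)
    spatial <- emg_spatial_model(protocol,
                                 activation = rotation_activation(protocol))
    rec <- apply_filter_chain(generate_session(protocol, spatial))
    wf <- extract_feature_tensor(rec, window_spec(fs = protocol$fs),
                                 time_steps = time_steps)
    folds <- make_trial_folds(wf$labels, wf$trial, k = reps,
                              rest_id = protocol$rest_id)
    te <- folds == reps
    xtr <- wf
    xtr$tensor <- wf$tensor[!te, , , , drop = FALSE]
    xtr$labels <- wf$labels[!te]
    xtr$window_labels <- wf$window_labels[!te, , drop = FALSE]
    accs <- vapply(c("stcn", "tcn"), function(kind) {
      dec <- fit_decoder(xtr, kind = kind, config = cfg,
                         classes = wf$classes, seed = seed + s)
      mean(predict(dec, wf$tensor[te, , , , drop = FALSE]) ==
             wf$labels[te])
    }, 0)
    rows[[s]] <- data.frame(seed = s, stcn = accs[["stcn"]],
                            tcn = accs[["tcn"]])
  }
  acc <- do.call(rbind, rows)
  dif <- acc$stcn - acc$tcn
  # ties in the paired accuracies preclude an exact p; the normal
  # approximation is intended here
  p <- if (all(dif == 0)) 1
       else suppressWarnings(
         stats::wilcox.test(acc$stcn[dif != 0], acc$tcn[dif != 0],
                            paired = TRUE,
                            alternative = "greater")$p.value)
  list(acc = acc, p_value = p)
}

#' Saliency channel-recovery experiment
#'
#' Trains the spatio-temporal network on sessions where each gesture's
#' active channels are known, computes per-gesture saliency maps, and asks
#' whether truly active channels rank above inactive ones in channel-mean
#' saliency (one-sided Mann-Whitney on the pooled ranks across seeds and
#' gestures).
#'
#' @param n_seeds replicates.
#' @param gesture gesture class examined (default 1).
#' @param reps,move_s,rest_s,time_steps,epochs scale parameters as in
#'   \code{\link{spatial_advantage_experiment}}.
#' @param seed base seed.
#' @return list: \code{active_ranks}, \code{inactive_ranks} (pooled channel
#'   ranks, 1 = most salient), \code{p_value}.
#' @export
saliency_recovery_experiment <- function(n_seeds = 10L, gesture = 1L,
                                         reps = 3L, move_s = 2, rest_s = 1,
                                         time_steps = 10L, epochs = 15L,
                                         seed = 1L) {
  cfg <- stcn_config(n_blocks = 2L, dilations = c(1L, 2L), filters = 8L,
                     dropout_p = 0.1, epochs = epochs, patience = epochs,
                     lr = 1e-2)
  active_ranks <- c(); inactive_ranks <- c()
  for (s in seq_len(n_seeds)) {
    protocol <- emg_protocol(reps_per_gesture = reps, move_s = move_s,
                             rest_s = rest_s, seed = seed + 977L * s)
    act <- rotation_activation(protocol)
    spatial <- emg_spatial_model(protocol, activation = act)
    rec <- apply_filter_chain(generate_session(protocol, spatial))
    wf <- extract_feature_tensor(rec, window_spec(fs = protocol$fs),
                                 time_steps = time_steps)
    dec <- fit_decoder(wf, kind = "stcn", config = cfg, seed = seed + s)
    maps <- saliency_maps(dec, wf, gestures = gesture, max_samples = 10L)
    ch_score <- colMeans(maps[[1]]$scores)
    rk <- rank(-ch_score)  # 1 = most salient
    on_ch <- which(act[gesture, ] > 0)
    active_ranks <- c(active_ranks, rk[on_ch])
    inactive_ranks <- c(inactive_ranks, rk[-on_ch])
  }
  p <- stats::wilcox.test(active_ranks, inactive_ranks,
                          alternative = "less", exact = FALSE)$p.value
  list(active_ranks = active_ranks, inactive_ranks = inactive_ranks,
       p_value = p)
}
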