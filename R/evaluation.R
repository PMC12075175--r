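#' Trial-wise stratified cross-validation folds
#'
#' Assigns each trial of every gesture to a fold round-robin (within
#' gesture, in trial order), so all windows of a trial stay in one fold and
#' folds are stratified by class.
#'
#' @param labels per-sample class labels (one per model sample).
#' @param trial trial index per sample.
#' @param k number of folds.
#' @param rest_id optional rest class id: a trial's class is then its
#'   dominant movement label (rest sequences stay with their trial).
#' @return integer fold id per sample.
#' @export
make_trial_folds <- function(labels, trial, k = 5L, rest_id = NULL) {
  k <- as.integer(k)
  tr_ids <- sort(unique(trial))
  cls_of_trial <- vapply(tr_ids, function(id) {
    labs <- labels[trial == id]
    if (!is.null(rest_id)) {
      nr <- labs[labs != rest_id]
      if (length(nr)) labs <- nr
    }
    as.integer(names(which.max(table(labs))))
  }, 0L)
  fold_of <- integer(length(tr_ids))
  for (g in unique(cls_of_trial)) {
    sel <- which(cls_of_trial == g)
    # pure-rest trials need no stratification guarantee: rest samples are
    # abundant in every movement trial already
    if (length(sel) < k && !(identical(g, rest_id) || g %in% rest_id))
      stop(sprintf("class %s has %d trials, fewer than %d folds",
                   g, length(sel), k))
    fold_of[sel] <- rep_len(seq_len(k), length(sel))
  }
  fold_of[match(trial, tr_ids)]
}

#' Cross-validated decoding accuracy for one subject session
#'
#' Runs the full per-subject pipeline the decoders are compared on: density
#' selection, filter chain, feature-tensor extraction, trial-wise stratified
#' k-fold fitting and testing. Standardization statistics come from each
#' training fold only.
#'
#' @param rec an \code{\link{emg_recording}} (one subject session).
#' @param kind decoder type, see \code{\link{fit_decoder}}.
#' @param density \code{"medium"} or \code{"low"}.
#' @param k folds.
#' @param wspec,fcfg,time_steps feature extraction settings.
#' @param config decoder configuration.
#' @param filter apply the band-pass + notch chain first.
#' @param seed RNG seed for fold-model fits.
#' @return list with \code{accuracy} (mean over folds), \code{per_fold},
#'   \code{preds}, \code{labels}.
#' @export
cross_validate <- function(rec, kind = "lda", density = "medium", k = 5L,
                           wspec = window_spec(fs = rec$fs),
                           fcfg = feature_config(), time_steps = 60L,
                           config = NULL, filter = TRUE, seed = 1L) {
  stopifnot(inherits(rec, "emg_recording"))
  rec <- select_density(rec, density)
  if (filter) rec <- apply_filter_chain(rec)
  wf <- extract_feature_tensor(rec, wspec, fcfg, time_steps)
  rest_id <- if ("rest" %in% wf$classes) match("rest", wf$classes)
             else length(wf$classes)
  folds <- make_trial_folds(wf$labels, wf$trial, k, rest_id = rest_id)
  preds <- integer(length(wf$labels))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    xtr <- wf
    xtr$tensor <- wf$tensor[tr, , , , drop = FALSE]
    xtr$labels <- wf$labels[tr]
    xtr$window_labels <- wf$window_labels[tr, , drop = FALSE]
    dec <- fit_decoder(xtr, kind = kind, config = config,
                       classes = wf$classes, seed = seed + f)
    p <- predict(dec, wf$tensor[te, , , , drop = FALSE])
    preds[te] <- p
    acc[f] <- mean(p == wf$labels[te])
  }
  list(accuracy = mean(acc), per_fold = acc, preds = preds,
       labels = wf$labels, classes = wf$classes)
}

#' Accuracy table over subjects, decoders and densities
#'
#' @param sessions named list of \code{\link{emg_recording}}s (one per
#'   subject).
#' @param kinds decoder types to evaluate.
#' @param densities density configurations.
#' @param ... forwarded to \code{\link{cross_validate}}.
#' @return data frame with columns \code{subject}, \code{decoder},
#'   \code{density}, \code{accuracy}.
#' @export
evaluate_sessions <- function(sessions, kinds = "lda",
                              densities = c("medium", "low"), ...) {
  if (is.null(names(sessions)))
    names(sessions) <- sprintf("S%02d", seq_along(sessions))
  rows <- list()
  for (s in names(sessions)) for (kd in kinds) for (dn in densities) {
    cv <- cross_validate(sessions[[s]], kind = kd, density = dn, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, decoder = kd, density = dn, accuracy = cv$accuracy)
  }
  do.call(rbind, rows)
}

#' Confusion matrix
#'
#' @param preds predicted class ids.
#' @param labels true class ids.
#' @param classes class names (length = number of classes).
#' @param normalize row-normalize (rows sum to 1; all-zero rows stay zero).
#' @return square matrix, true classes in rows.
#' @export
confusion <- function(preds, labels, classes, normalize = FALSE) {
  stopifnot(length(preds) == length(labels))
  K <- length(classes)
  if (any(preds < 1 | preds > K) || any(labels < 1 | labels > K))
    stop("class id outside 1..", K)
  m <- matrix(0, K, K, dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(preds)) m[labels[i], preds[i]] <- m[labels[i], preds[i]] + 1
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Nemenyi post-hoc pairwise comparison
#'
#' Rank-based all-pairs comparison after a significant Friedman test:
#' within-subject ranks are averaged per condition and the rank differences
#' referred to the studentized range distribution
#' (\eqn{q = |\bar R_i - \bar R_j| / \sqrt{k(k+1)/(12n)}}, df = Inf).
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns.
#' @return symmetric matrix of pairwise p-values.
#' @export
nemenyi_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  p <- matrix(1, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    q <- abs(rbar[i] - rbar[j]) / se
    p[i, j] <- p[j, i] <- 1 - stats::ptukey(q, nmeans = k, df = Inf)
  }
  p
}

#' Nonparametric comparison of densities and decoders
#'
#' The statistical bundle of the medium- vs low-density study: a paired
#' Wilcoxon signed-rank test of medium vs low accuracy (paired over
#' subject-decoder combinations; exact p for small samples, zero
#' differences dropped), a Friedman test across decoders at medium density
#' (df = decoders - 1), and -- when the Friedman test is significant at 0.05
#' and at least three decoders are present -- Nemenyi pairwise p-values.
#'
#' @param acc_table data frame from \code{\link{evaluate_sessions}}.
#' @return object of class \code{emg_comparison}: fields \code{wilcoxon}
#'   (statistic \code{V}, \code{p}), \code{friedman} (\code{chisq},
#'   \code{df}, \code{p}), \code{nemenyi} (matrix or NULL),
#'   \code{medium_mean}, \code{low_mean}.
#' @export
compare_conditions <- function(acc_table) {
  stopifnot(all(c("subject", "decoder", "density", "accuracy") %in%
                  names(acc_table)))
  n_subj <- length(unique(acc_table$subject))
  if (n_subj < 6L)
    warning("fewer than 6 subjects: tests are underpowered")
  out <- list(wilcoxon = NULL, friedman = NULL, nemenyi = NULL)

  if (all(c("medium", "low") %in% acc_table$density)) {
    med <- acc_table[acc_table$density == "medium", ]
    low <- acc_table[acc_table$density == "low", ]
    key <- function(d) paste(d$subject, d$decoder)
    low <- low[match(key(med), key(low)), ]
    dif <- med$accuracy - low$accuracy
    keep <- dif != 0
    wt <- if (any(keep))
      stats::wilcox.test(med$accuracy[keep], low$accuracy[keep],
                         paired = TRUE, exact = length(dif[keep]) <= 50)
    else list(statistic = c(V = NA_real_), p.value = 1)
    out$wilcoxon <- list(V = unname(wt$statistic), p = wt$p.value,
                         n_pairs = sum(keep))
    out$medium_mean <- mean(med$accuracy)
    out$low_mean <- mean(low$accuracy)
  }

  decs <- unique(acc_table$decoder)
  if (length(decs) >= 2L) {
    dens0 <- if ("medium" %in% acc_table$density) "medium"
             else acc_table$density[1]
    sub <- acc_table[acc_table$density == dens0, ]
    m <- stats::reshape(sub[, c("subject", "decoder", "accuracy")],
                        idvar = "subject", timevar = "decoder",
                        direction = "wide")
    mat <- as.matrix(m[, -1, drop = FALSE])
    colnames(mat) <- sub("^accuracy\\.", "", colnames(mat))
    ft <- stats::friedman.test(mat)
    chisq <- unname(ft$statistic); pval <- ft$p.value
    if (!is.finite(chisq)) { chisq <- 0; pval <- 1 }  # fully tied rows
    out$friedman <- list(chisq = chisq, df = unname(ft$parameter), p = pval)
    if (ncol(mat) >= 3L && is.finite(ft$p.value) && ft$p.value < 0.05)
      out$nemenyi <- nemenyi_test(mat)
  }
  class(out) <- "emg_comparison"
  out
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat("Density / decoder comparison\n")
  if (!is.null(x$wilcoxon)) {
    cat(sprintf(
      "  medium vs low: mean accuracy %.3f vs %.3f; Wilcoxon V = %g, p = %.3g\n",
      x$medium_mean, x$low_mean, x$wilcoxon$V, x$wilcoxon$p))
  }
  if (!is.null(x$friedman))
    cat(sprintf("  decoders: Friedman chi^2 = %.3g, df = %d, p = %.3g\n",
                x$friedman$chisq, x$friedman$df, x$friedman$p))
  if (!is.null(x$nemenyi)) {
    cat("  Nemenyi pairwise p-values:\n")
    print(round(x$nemenyi, 4))
  }
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' One session per subject with subject-specific seeds and mild
#' multiplicative jitter on the activation gains (inter-subject
#' variability).
#'
#' @param n_subjects cohort size.
#' @param protocol an \code{\link{emg_protocol}} (its seed is the cohort
#'   base seed).
#' @param spatial an \code{\link{emg_spatial_model}}.
#' @param gain_jitter half-width of the uniform gain jitter.
#' @return named list of \code{\link{emg_recording}}s.
#' @export
simulate_subjects <- function(n_subjects = 10L, protocol = emg_protocol(),
                              spatial = emg_spatial_model(protocol),
                              gain_jitter = 0.1) {
  sessions <- list()
  for (s in seq_len(n_subjects)) {
    p_s <- protocol
    p_s$seed <- protocol$seed + 1000L * s
    set.seed(p_s$seed)
    act <- spatial$activation *
      matrix(stats::runif(length(spatial$activation), 1 - gain_jitter,
                          1 + gain_jitter),
             nrow(spatial$activation))
    act[protocol$rest_id, ] <- 0
    sp_s <- spatial
    sp_s$activation <- act
    sessions[[sprintf("S%02d", s)]] <-
      generate_session(p_s, sp_s, subject = sprintf("S%02d", s))
  }
  sessions
}
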