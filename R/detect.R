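#' Double-threshold detection configuration
#'
#' The detector rectifies the signal, smooths it with a centred moving
#' average of \code{m} samples, and estimates baseline statistics
#' (\eqn{\mu_n}, \eqn{\sigma_n}) from the quietest \code{baseline_s}-second
#' stretch of the recording. Two thresholds are derived:
#' \eqn{LT = \mu_n + k_1\sigma_n} (candidate activity) and
#' \eqn{UT = \mu_n + k_2\sigma_n} (confirmation). A candidate run above LT
#' becomes an ON state only if it lasts at least \code{m} samples and
#' contains an excursion above UT; shorter variations are rejected.
#'
#' @param k1,k2 threshold multipliers, \code{k1 < k2}.
#' @param m minimum run length in samples (also the smoothing span); about
#'   28 ms at 1,067 Hz with the default 30.
#' @param baseline_s length of the baseline segment used for
#'   \eqn{\mu_n,\sigma_n}, seconds.
#' @return object of class \code{emg_detection_config}.
#' @export
detection_config <- function(k1 = 3, k2 = 5, m = 30L, baseline_s = 1) {
  if (k1 >= k2) stop("need k1 < k2")
  if (m < 1L) stop("m must be >= 1")
  if (baseline_s <= 0) stop("baseline_s must be positive")
  structure(list(k1 = k1, k2 = k2, m = as.integer(m),
                 baseline_s = baseline_s),
            class = "emg_detection_config")
}

# quietest baseline_s-second stretch (coarse grid search over raw variance)
.find_baseline <- function(x, n_base) {
  n <- length(x)
  if (n_base > n) n_base <- n
  step <- max(1L, n_base %/% 4L)
  starts <- unique(c(seq.int(1L, n - n_base + 1L, by = step), n - n_base + 1L))
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x ^ 2))
  sums <- cs[starts + n_base] - cs[starts]
  sq <- cs2[starts + n_base] - cs2[starts]
  v <- (sq - sums ^ 2 / n_base) / (n_base - 1)
  s <- starts[which.min(v)]
  s:(s + n_base - 1L)
}

#' ON/OFF segmentation of a single channel
#'
#' @param x numeric vector, one raw (unrectified) channel.
#' @param cfg a \code{\link{detection_config}}.
#' @param fs sampling rate, Hz.
#' @param refine re-estimate the baseline statistics from the pooled OFF
#'   states of a first detection pass (default). The initial
#'   quietest-stretch estimate is biased low by its minimum-variance
#'   selection; the pooled pass removes that bias.
#' @return object of class \code{emg_activity}: \code{states} (data frame
#'   \code{state, start, end, variance} with alternating ON/OFF states tiling
#'   the signal; variances are of the raw signal), the thresholds \code{lt},
#'   \code{ut}, baseline statistics, and \code{fs}.
#' @export
detect_on_off <- function(x, cfg = detection_config(), fs, refine = TRUE) {
  if (missing(fs) || fs <= 0) stop("fs required")
  n_base <- round(cfg$baseline_s * fs)
  if (n_base < 100L)
    stop("baseline segment shorter than 100 samples; increase baseline_s")
  if (length(x) < n_base) stop("signal shorter than the baseline window")
  base_idx <- .find_baseline(x, n_base)
  mu_raw <- mean(x[base_idx])
  r <- abs(x - mu_raw)
  # centred moving average: envelope on the same scale as the rectified signal
  m <- cfg$m
  env <- as.numeric(stats::filter(r, rep(1 / m, m), sides = 2))
  env[is.na(env)] <- r[is.na(env)]
  mu_n <- mean(env[base_idx])
  sd_n <- stats::sd(env[base_idx])
  if (sd_n <= .Machine$double.eps * max(1, abs(mu_n)))
    stop("zero-variance baseline segment")

  run_detector <- function(mu_n, sd_n) {
    lt <- mu_n + cfg$k1 * sd_n
    ut <- mu_n + cfg$k2 * sd_n
    above <- env > lt
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    on_mask <- logical(length(x))
    for (i in seq_along(rl$values)) {
      if (!rl$values[i] || rl$lengths[i] < m) next
      seg <- starts[i]:ends[i]
      # confirmation: sustained supra-UT activity (>= m consecutive samples),
      # not a single-sample excursion -- the rectified-noise envelope is
      # right-skewed, so isolated threshold spikes are not evidence of
      # contraction
      ru <- rle(env[seg] > ut)
      if (any(ru$values & ru$lengths >= m)) on_mask[seg] <- TRUE
    }
    # variations of the detector output shorter than m samples are
    # rejected in both directions: OFF gaps inside a contraction are
    # merged first, then stray short ON runs dropped
    rl <- rle(on_mask)
    if (length(rl$lengths) > 1L) {
      gap <- which(!rl$values & rl$lengths < m)
      gap <- gap[gap > 1L & gap < length(rl$values)]
      if (length(gap)) {
        e <- cumsum(rl$lengths); s <- e - rl$lengths + 1L
        for (i in gap) on_mask[s[i]:e[i]] <- TRUE
        rl <- rle(on_mask)
      }
      short_on <- which(rl$values & rl$lengths < m)
      if (length(short_on)) {
        e <- cumsum(rl$lengths); s <- e - rl$lengths + 1L
        for (i in short_on) on_mask[s[i]:e[i]] <- FALSE
      }
    }
    list(on_mask = on_mask, lt = lt, ut = ut)
  }

  det <- run_detector(mu_n, sd_n)
  if (refine && any(!det$on_mask)) {
    off_env <- env[!det$on_mask]
    mu2 <- mean(off_env); sd2 <- stats::sd(off_env)
    if (is.finite(sd2) && sd2 > 0) {
      mu_n <- mu2; sd_n <- sd2
      det <- run_detector(mu_n, sd_n)
    }
  }
  lt <- det$lt; ut <- det$ut
  # the centred smoother leaves half a window unclassifiable at each edge;
  # the analyzed span excludes it
  half <- m %/% 2L
  span <- (half + 1L):(length(x) - half)
  rl2 <- rle(det$on_mask[span])
  e2 <- cumsum(rl2$lengths) + half
  s2 <- e2 - rl2$lengths + 1L
  states <- data.frame(
    state = ifelse(rl2$values, "ON", "OFF"),
    start = s2, end = e2)
  # per-state raw-signal variance; interiors only (a guard band of m samples
  # at each boundary keeps transition samples from contaminating the state)
  states$variance <- vapply(seq_len(nrow(states)), function(i) {
    a <- states$start[i]; b <- states$end[i]
    if (b - a + 1L > 3L * m) { a <- a + m; b <- b - m }
    seg <- x[a:b]
    if (length(seg) < 2L) return(0) else stats::var(seg)
  }, 0)
  structure(list(states = states, lt = lt, ut = ut, mu_n = mu_n,
                 sd_n = sd_n, baseline = range(base_idx), fs = fs),
            class = "emg_activity")
}

#' @export
print.emg_activity <- function(x, ...) {
  n_on <- sum(x$states$state == "ON")
  cat(sprintf(
    "Activity segmentation: %d ON / %d OFF states (LT %.3g, UT %.3g)\n",
    n_on, sum(x$states$state == "OFF"), x$lt, x$ut))
  invisible(x)
}

#' Signal-to-noise ratio from an ON/OFF segmentation
#'
#' \eqn{SNR = 10\log_{10}(\sigma_s^2/\sigma_n^2 - 1)} where
#' \eqn{\sigma_s^2} and \eqn{\sigma_n^2} are the mean per-state variances of
#' the ON and OFF states (raw-signal variances; rectification is used only
#' for detection). Also reports the baseline noise level
#' \eqn{e_n = \frac{1}{N}\sum_i \sigma_{n_i}}, the mean OFF-state standard
#' deviation. When \eqn{\sigma_s^2 \le \sigma_n^2} the ratio has no dB value
#' and the result is flagged with \code{snr_db = -Inf}.
#'
#' @param seg an \code{\link{detect_on_off}} result, or a list with numeric
#'   fields \code{on_var} and \code{off_var} (mean state variances).
#' @return list with \code{snr_db}, \code{sigma_s2}, \code{sigma_n2},
#'   \code{e_n}, \code{n_on}, \code{n_off}, \code{flagged}.
#' @export
compute_snr <- function(seg) {
  if (inherits(seg, "emg_activity")) {
    on <- seg$states[seg$states$state == "ON", ]
    off <- seg$states[seg$states$state == "OFF", ]
    if (nrow(on) < 1L || nrow(off) < 1L)
      return(list(snr_db = -Inf, sigma_s2 = NA_real_, sigma_n2 = NA_real_,
                  e_n = if (nrow(off)) mean(sqrt(off$variance)) else NA_real_,
                  n_on = nrow(on), n_off = nrow(off), flagged = TRUE))
    s2 <- mean(on$variance); n2 <- mean(off$variance)
    e_n <- mean(sqrt(off$variance))
    n_on <- nrow(on); n_off <- nrow(off)
  } else {
    s2 <- mean(seg$on_var); n2 <- mean(seg$off_var)
    e_n <- mean(sqrt(seg$off_var))
    n_on <- length(seg$on_var); n_off <- length(seg$off_var)
  }
  if (!is.finite(s2) || !is.finite(n2) || n2 <= 0 || s2 <= n2)
    return(list(snr_db = -Inf, sigma_s2 = s2, sigma_n2 = n2, e_n = e_n,
                n_on = n_on, n_off = n_off, flagged = TRUE))
  list(snr_db = 10 * log10(s2 / n2 - 1), sigma_s2 = s2, sigma_n2 = n2,
       e_n = e_n, n_on = n_on, n_off = n_off, flagged = FALSE)
}

#' Per-channel average SNR table
#'
#' Runs the double-threshold detector and the SNR computation on every
#' channel of a recording.
#'
#' @param rec an \code{\link{emg_recording}}.
#' @param cfg a \code{\link{detection_config}}.
#' @return data frame with columns \code{channel}, \code{snr_db},
#'   \code{e_n}, \code{n_on}, \code{n_off}, \code{flagged}. Channels where
#'   detection fails are flagged with \code{NA} SNR rather than aborting the
#'   whole report.
#' @export
snr_report <- function(rec, cfg = detection_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  rows <- lapply(seq_len(ncol(rec$data)), function(ch) {
    res <- tryCatch({
      seg <- detect_on_off(rec$data[, ch], cfg, fs = rec$fs)
      compute_snr(seg)
    }, error = function(e) list(snr_db = NA_real_, e_n = NA_real_,
                                n_on = NA_integer_, n_off = NA_integer_,
                                flagged = TRUE))
    data.frame(channel = ch, snr_db = res$snr_db, e_n = res$e_n,
               n_on = res$n_on, n_off = res$n_off, flagged = res$flagged)
  })
  do.call(rbind, rows)
}
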