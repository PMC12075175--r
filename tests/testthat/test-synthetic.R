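test_that("default protocol schedules 60 movement trials of exact length", {
  p <- emg_protocol()
  sched <- generate_trial_schedule(p)
  expect_equal(nrow(sched), 60L)
  expect_true(all(sched$end - sched$start + 1L == 6402L))  # 6 s at 1067 Hz
  # non-overlapping, ordered, every gesture 10 times
  expect_true(all(diff(sched$start) > 0))
  expect_true(all(sched$start[-1] > sched$end[-nrow(sched)]))
  expect_equal(as.integer(table(sched$gesture)), rep(10L, 6L))
  # each block holds every gesture once
  for (b in unique(sched$block))
    expect_setequal(sched$gesture[sched$block == b], 1:6)
})

test_that("degenerate and invalid protocols are handled", {
  p1 <- emg_protocol(n_gestures = 2L, reps_per_gesture = 1L)
  s1 <- generate_trial_schedule(p1)
  expect_equal(nrow(s1), 2L)
  expect_equal(s1$end[1] - s1$start[1] + 1L, round(6 * 1067))
  expect_error(emg_protocol(move_s = 0), "move_s")
  expect_error(emg_protocol(rest_s = -1), "rest_s")
  expect_error(emg_protocol(fs = 500), "fs")
  expect_error(emg_protocol(n_nodes = 0), "channel count")
})

test_that("sessions have exact label accounting and are seed-reproducible", {
  ts <- tiny_session()
  p <- ts$protocol
  rec <- ts$rec
  move_len <- round(p$move_s * p$fs)
  sched <- generate_trial_schedule(p)
  n_move_trials <- sum(sched$gesture != p$rest_id)
  expect_equal(sum(rec$labels != p$rest_id), n_move_trials * move_len)
  expect_equal(nrow(rec$data),
               nrow(sched) * (move_len + round(p$rest_s * p$fs)))
  rec2 <- generate_session(p)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$labels, rec2$labels)
  p3 <- p; p3$seed <- p$seed + 1L
  rec3 <- generate_session(p3)
  expect_false(identical(rec$data, rec3$data))
})

test_that("zero-activation channels carry pure baseline noise", {
  p <- emg_protocol(n_gestures = 2L, reps_per_gesture = 5L, move_s = 2,
                    rest_s = 1, n_nodes = 2L, channels_per_node = 1L,
                    seed = 21L)
  # channel 1 active, channel 2 silent for the movement class
  sp <- emg_spatial_model(p, activation = matrix(c(1, 0, 0, 0), 2, 2),
                          noise_floor_sd = 1.5, node_correlation = 0)
  rec <- generate_session(p, sp)
  sched <- generate_trial_schedule(p)
  on_idx <- unlist(Map(seq, sched$start[sched$gesture == 1],
                       sched$end[sched$gesture == 1]))
  # silent channel: ON-state variance equal to the noise floor (F test)
  ft <- stats::var.test(rec$data[on_idx, 2],
                        rec$data[rec$labels == p$rest_id, 2])
  expect_gt(ft$p.value, 0.01)
  expect_equal(stats::var(rec$data[on_idx, 2]), 1.5 ^ 2, tolerance = 0.05)
  # active channel realises the variance-ratio SNR target:
  # 10*log10(ratio - 1) = 9.54 dB <=> ratio ~ 10
  ratio <- stats::var(rec$data[on_idx, 1]) /
    stats::var(rec$data[rec$labels == p$rest_id, 1])
  expect_equal(ratio, 1 + 10 ^ 0.954, tolerance = 0.1)
})

test_that("rest-only model gives noise-floor variance everywhere", {
  p <- emg_protocol(n_gestures = 2L, reps_per_gesture = 3L, move_s = 2,
                    rest_s = 1, n_nodes = 1L, channels_per_node = 1L,
                    seed = 5L)
  expect_warning(
    sp <- emg_spatial_model(p, activation = matrix(0, 2, 1),
                            noise_floor_sd = 0.7),
    "all-zero")
  rec <- generate_session(p, sp)
  expect_equal(stats::var(rec$data[, 1]), 0.7 ^ 2, tolerance = 0.05)
})

test_that("carrier power is concentrated in the synthesis band", {
  p <- emg_protocol(n_gestures = 2L, reps_per_gesture = 1L, move_s = 6,
                    rest_s = 1, n_nodes = 1L, channels_per_node = 1L,
                    seed = 9L)
  # a high SNR target makes the additive white floor negligible, so the
  # movement segment is essentially pure carrier
  sp <- emg_spatial_model(p, activation = matrix(c(1, 0), 2, 1),
                          snr_target_db = 40, ramp_s = 0)
  rec <- generate_session(p, sp)
  sched <- generate_trial_schedule(p)
  seg <- rec$data[(sched$start[sched$gesture == 1][1] + 200):
                    (sched$end[sched$gesture == 1][1] - 200), 1]
  # tapered, unpadded periodogram: an untapered zero-padded estimate leaks
  # in-band power into the tails
  pg <- stats::spec.pgram(stats::ts(seg, frequency = p$fs), plot = FALSE,
                          taper = 0.1, fast = FALSE)
  inband <- pg$freq >= 30 & pg$freq <= 350
  expect_gt(sum(pg$spec[inband]) / sum(pg$spec), 0.95)
})

test_that("spatial model validation catches inconsistent inputs", {
  p <- emg_protocol()
  expect_error(emg_spatial_model(p, activation = matrix(1, 2, 2)),
               "n_gestures x n_channels")
  act <- default_activation(p)
  act[p$rest_id, 1] <- 0.5
  expect_error(emg_spatial_model(p, activation = act), "rest")
  expect_error(emg_spatial_model(p, carrier_band = c(30, 600)),
               "carrier_band")
  expect_error(emg_spatial_model(p, noise_floor_sd = 0), "noise_floor_sd")
})
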