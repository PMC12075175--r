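test_that("trial-wise folds keep whole trials together and stratify classes", {
  labels <- rep(c(1L, 2L, 1L, 2L, 1L, 2L), each = 10L)
  trial <- rep(1:6, each = 10L)
  folds <- make_trial_folds(labels, trial, k = 3L)
  expect_equal(length(folds), 60L)
  for (tr in 1:6)
    expect_equal(length(unique(folds[trial == tr])), 1L)
  for (f in 1:3)
    expect_setequal(unique(labels[folds == f]), c(1L, 2L))
  expect_error(make_trial_folds(labels, trial, k = 4L), "fewer than")
})

test_that("cross-validation recovers separable synthetic gestures", {
  p <- emg_protocol(reps_per_gesture = 3L, move_s = 1.5, rest_s = 0.8,
                    seed = 31L)
  rec <- generate_session(p)
  cv <- cross_validate(rec, kind = "lda", density = "medium", k = 3L,
                       time_steps = 10L)
  expect_gte(cv$accuracy, 0.9)
  expect_length(cv$per_fold, 3L)
  expect_error(cross_validate(rec, kind = "lda", k = 10L), "fewer than")
})

test_that("trial-level label shuffling drops accuracy to chance", {
  p <- emg_protocol(reps_per_gesture = 5L, move_s = 1, rest_s = 0.6,
                    seed = 37L)
  rec <- generate_session(p)
  # shuffle gestures between trials: relabel each movement trial's samples
  sched <- generate_trial_schedule(p)
  set.seed(12)
  relab <- rec$labels
  newg <- sample(sched$gesture)
  for (i in seq_len(nrow(sched)))
    relab[sched$start[i]:sched$end[i]] <- newg[i]
  rec2 <- emg_recording(rec$data, rec$fs, relab, rec$channel_map, rec$meta)
  cv <- cross_validate(rec2, kind = "lda", density = "medium", k = 3L,
                       time_steps = 10L)
  # movement classes are uninformative; rest stays identifiable, so chance
  # is evaluated on movement samples only
  mv <- cv$labels != 6L
  expect_lt(abs(mean(cv$preds[mv] == cv$labels[mv]) - 1 / 6), 0.12)
})

test_that("confusion matrices count, normalize and validate", {
  expect_equal(confusion(c(1L, 2L, 3L), c(1L, 2L, 3L), classes = letters[1:3]),
               diag(3), ignore_attr = TRUE)
  set.seed(4)
  n <- 6000L
  preds <- sample(1:6, n, replace = TRUE)
  labels <- sample(1:6, n, replace = TRUE)
  cm <- confusion(preds, labels, classes = as.character(1:6),
                  normalize = TRUE)
  expect_equal(rowSums(cm), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(cm - 1 / 6)), 0.04)
  one <- confusion(2L, 1L, classes = c("a", "b"))
  expect_equal(sum(one), 1)
  expect_equal(one["a", "b"], 1)
  expect_error(confusion(7L, 1L, classes = as.character(1:6)), "outside")
})

test_that("Wilcoxon p-values match exact sign-pattern enumeration", {
  # textbook case: five positive differences
  d <- c(1, 2, 3, 4, 5)
  expect_equal(oracle_signrank_p(d, "greater"), 1 / 32)
  wt <- stats::wilcox.test(d, alternative = "greater")
  expect_equal(wt$p.value, 1 / 32)
  set.seed(10)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(unique(abs(d))) < length(d)) next  # oracle assumes no ties
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(stats::wilcox.test(d, alternative = alt)$p.value,
                   oracle_signrank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("Friedman statistic matches the rank formula and df convention", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    mat <- matrix(rnorm(n * 3), n, 3)
    ft <- stats::friedman.test(mat)
    expect_equal(unname(ft$statistic), oracle_friedman_chisq(mat),
                 tolerance = 1e-10)
    expect_equal(unname(ft$parameter), 2)
  }
})

test_that("Nemenyi p-values behave like a rank post-hoc should", {
  set.seed(12)
  # identical columns: all pairwise p = 1
  m0 <- matrix(rnorm(8), 8, 3)
  expect_true(all(nemenyi_test(cbind(m0[, 1], m0[, 1], m0[, 1])) == 1))
  # one clearly better condition: its pairwise p-values are smallest
  m <- matrix(rnorm(30), 10, 3)
  m[, 3] <- m[, 3] + 10
  p <- nemenyi_test(m)
  expect_true(isSymmetric(p))
  expect_lt(p[1, 3], 0.05)
  expect_gt(p[1, 2], p[1, 3])
})

test_that("compare_conditions assembles the statistics bundle", {
  set.seed(13)
  subjects <- sprintf("S%02d", 1:8)
  tab <- expand.grid(subject = subjects,
                     decoder = c("lda", "tcn", "stcn"),
                     density = c("medium", "low"),
                     stringsAsFactors = FALSE)
  base <- runif(nrow(tab), 0.6, 0.8)
  tab$accuracy <- base +
    ifelse(tab$density == "medium", 0.1, 0) +
    ifelse(tab$decoder == "stcn", 0.05, 0)
  cmp <- compare_conditions(tab)
  expect_lt(cmp$wilcoxon$p, 0.05)
  expect_equal(cmp$friedman$df, 2)
  expect_gt(cmp$medium_mean, cmp$low_mean)

  # identical paired samples: no detectable difference
  tab2 <- tab
  tab2$accuracy <- rep(base[tab$density == "medium"], 2)
  cmp2 <- compare_conditions(tab2)
  expect_equal(cmp2$wilcoxon$p, 1)

  # identical decoder columns: Friedman p = 1 at df = 2
  tab3 <- tab
  tab3$accuracy <- rep(runif(length(subjects)), 6)
  cmp3 <- compare_conditions(tab3)
  expect_equal(cmp3$friedman$p, 1)
  expect_equal(cmp3$friedman$df, 2)

  expect_warning(compare_conditions(tab[tab$subject %in% subjects[1:4], ]),
                 "underpowered")
})
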