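mk_trials <- function(rt, correct = 1L) {
  tibble::tibble(
    participant_id = "p1", food_id = "f", small = 100, large = 120,
    rep = seq_along(rt), larger_side = "left", response_side = "left",
    correct = as.integer(correct), rt_ms = rt
  )
}

test_that("RT trimming applies the floor then the pooled outlier bound", {
  tr <- trim_rts(mk_trials(c(340, 360)), floor_ms = 350, k_sd = 3)
  expect_equal(tr$trials$rt_ms, 360)
  expect_equal(tr$report$n_removed_floor, 1)
  expect_equal(tr$report$n_removed_outlier, 0)

  # brute-force check of the worked vector: 100 trials at 1000 ms + one at
  # 10000 ms; the slow trial exceeds mean + 3 SD (threshold ~ 3776 ms)
  rts <- c(rep(1000, 100), 10000)
  tr2 <- trim_rts(mk_trials(rts), floor_ms = 350, k_sd = 3)
  oracle <- brute_force_trim(rts, 350, 3)
  expect_equal(tr2$report$threshold_ms, oracle$threshold)
  expect_equal(tr2$report$threshold_ms, 3775.814, tolerance = 1e-3)
  expect_equal(tr2$report$n_removed_outlier, 1)
  expect_equal(sort(tr2$trials$rt_ms), sort(rts[oracle$keep]))
})

test_that("trimming matches the brute-force filter on random fixtures", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(50:300, 1)
    rts <- exp(rnorm(n, 7.5, 0.6)) + 200
    rts[sample(n, 3)] <- runif(3, 100, 400)
    rts[sample(n, 2)] <- runif(2, 5000, 60000)
    trials <- mk_trials(rts)
    tr <- trim_rts(trials, 350, 3)
    oracle <- brute_force_trim(rts, 350, 3)
    expect_equal(sort(tr$trials$rt_ms), sort(rts[oracle$keep]))
    r <- tr$report
    expect_equal(r$n_input, r$n_removed_floor + r$n_removed_outlier +
                   nrow(tr$trials))
    expect_equal(r$loss_proportion,
                 (r$n_removed_floor + r$n_removed_outlier) / r$n_input)
  }
})

test_that("re-trimming retained data removes nothing at the floor stage", {
  set.seed(73)
  rts <- c(runif(20, 100, 349), exp(rnorm(400, 7.8, 0.5)) + 300)
  tr <- trim_rts(mk_trials(rts), 350, 3)
  tr2 <- trim_rts(tr$trials, 350, 3)
  expect_equal(tr2$report$n_removed_floor, 0)
})

test_that("a clean narrow-RT generator loses nothing to trimming", {
  cfg <- cohort_config(n_participants = 10, t0_ms = 400, sigma_rt = 0.05,
                       p_anticipatory = 0, p_outlier = 0, seed = 79)
  panel <- sample_participants(cfg)
  trials <- simulate_discrimination(panel, build_pairs(study_grids(2), 20), cfg)
  tr <- trim_rts(trials)
  expect_equal(tr$report$loss_proportion, 0)
})

test_that("per-participant trimming scope computes separate bounds", {
  slow <- mk_trials(c(rep(1000, 50), 4000))
  fast <- dplyr::mutate(mk_trials(c(rep(500, 50), 4000)),
                        participant_id = "p2")
  both <- dplyr::bind_rows(slow, fast)
  pooled <- trim_rts(both, 350, 3, scope = "pooled")
  per <- trim_rts(both, 350, 3, scope = "participant")
  # per-participant bounds catch both 4000 ms trials; the pooled bound is
  # inflated by the between-participant spread
  expect_equal(per$report$n_removed_outlier, 2)
  expect_true(is.na(per$report$threshold_ms))
  expect_lte(pooled$report$n_removed_outlier, 2)
})

test_that("pair performance aggregates accuracy and correct-trial RT", {
  trials <- dplyr::bind_rows(
    mk_trials(rep(600, 10), correct = 1L),
    dplyr::mutate(mk_trials(c(500, 700, 900, 1100), correct = c(1L, 1L, 0L, 0L)),
                  small = 200, large = 220)
  )
  perf <- pair_performance(trials)
  p1 <- perf[perf$small == 100, ]
  expect_equal(p1$accuracy, 1)
  expect_equal(p1$mean_rt_correct, 600)
  p2 <- perf[perf$small == 200, ]
  expect_equal(p2$accuracy, 0.5)
  expect_equal(p2$mean_rt_correct, 600)

  # all-incorrect cells yield a missing RT
  bad <- dplyr::mutate(mk_trials(rep(800, 4)), correct = 0L)
  expect_message(perf_bad <- pair_performance(bad), "no correct trials")
  expect_equal(perf_bad$accuracy, 0)
  expect_true(is.na(perf_bad$mean_rt_correct))
})

test_that("simulated accuracy matches the generative link at a known pair", {
  cfg <- cohort_config(n_participants = 1, sigma_L = 0, sigma_U = 0,
                       mu_L = 80, mu_U = 160, cat_boost_b = 0,
                       weber_w = 0.2, acc_scale_a = 1.2, n_pair_reps = 500,
                       p_anticipatory = 0, p_outlier = 0, seed = 83)
  panel <- sample_participants(cfg)
  pairs <- tibble::tibble(food_id = "f", small = 100, large = 120, delta = 20)
  trials <- simulate_discrimination(panel, pairs, cfg)
  d <- 20 / (0.2 * 110)
  p <- plogis(1.2 * d)
  expect_lt(abs(mean(trials$correct) - p), 3 * sqrt(p * (1 - p) / 500))
})

test_that("accuracy declines with pair midpoint when there is no boost", {
  cfg <- cohort_config(n_participants = 60, cat_boost_b = 0, n_pair_reps = 10,
                       p_anticipatory = 0, p_outlier = 0, seed = 89)
  panel <- sample_participants(cfg)
  pairs <- build_pairs(build_grid(40, 300, 10, "f"), 20)
  trials <- simulate_discrimination(panel, pairs, cfg)
  acc <- dplyr::summarise(trials, acc = mean(correct),
                          .by = c("small"))
  acc <- acc[order(acc$small), ]
  # Weber monotonicity, allowing binomial jitter: fit must be decreasing in
  # the aggregate (first third clearly above last third)
  k <- nrow(acc)
  expect_gt(mean(acc$acc[1:8]), mean(acc$acc[(k - 7):k]) + 0.05)
  expect_lt(cor(acc$small, acc$acc, method = "spearman"), 0)
})

test_that("boundary-category performance detects a categorical boost", {
  cfg <- cohort_config(n_participants = 25, cat_boost_b = 1.5, weber_w = 0.3,
                       seed = 97)
  sim <- simulate_cohort(cfg)
  ranges <- suppressWarnings(individual_norm_ranges(sim$normality))
  tr <- trim_rts(sim$sizejudgment)
  perf <- suppressMessages(pair_performance(tr$trials))
  bp <- suppressMessages(performance_by_boundary(perf, ranges, log_rt = TRUE))
  m <- dplyr::summarise(bp$means, acc = mean(accuracy),
                        .by = "boundary_category")
  expect_gt(m$acc[m$boundary_category == "across_lower"],
            m$acc[m$boundary_category == "within"])
  expect_gt(m$acc[m$boundary_category == "across_upper"],
            m$acc[m$boundary_category == "within"])
  td <- generics::tidy(bp$accuracy)
  expect_lt(td$p_value[td$effect == "boundary_category"], 0.05)
  # the log transform is monotone: effect ordering agrees with raw RT
  raw <- generics::tidy(bp$rt)
  logged <- generics::tidy(bp$rt_log)
  expect_equal(sign(raw$statistic), sign(logged$statistic))
})

test_that("decomposition recovers null and positive categorical effects", {
  pairs <- build_pairs(study_grids(2), 20)
  # null boost: crossing coefficient within 3 SEs of zero
  cfg0 <- cohort_config(n_participants = 30, cat_boost_b = 0, seed = 101)
  sim0 <- simulate_cohort(cfg0)
  ranges0 <- suppressWarnings(individual_norm_ranges(sim0$normality))
  dec0 <- suppressMessages(
    weber_categorical_decomposition(trim_rts(sim0$sizejudgment)$trials, ranges0)
  )
  s0 <- dec0$summary
  cross0 <- s0[s0$model == "accuracy_logistic" & s0$term == "crossing", ]
  expect_lt(abs(cross0$estimate), 3 * cross0$se)
  weber0 <- s0[s0$model == "accuracy_logistic" & s0$term == "weber", ]
  expect_gt(weber0$estimate, 0)
  expect_lt(weber0$p_value, 0.001)

  # positive boost: crossing recovered as significantly positive
  cfg1 <- cohort_config(n_participants = 30, cat_boost_b = 1, seed = 103)
  sim1 <- simulate_cohort(cfg1)
  ranges1 <- suppressWarnings(individual_norm_ranges(sim1$normality))
  dec1 <- suppressMessages(
    weber_categorical_decomposition(trim_rts(sim1$sizejudgment)$trials, ranges1)
  )
  s1 <- dec1$summary
  cross1 <- s1[s1$model == "accuracy_logistic" & s1$term == "crossing", ]
  expect_gt(cross1$estimate, 0)
  expect_lt(cross1$p_value, 0.01)
  # faster correct responses on crossing pairs (RT decreases in d)
  rt1 <- s1[s1$model == "log_rt_linear" & s1$term == "crossing", ]
  expect_lt(rt1$estimate, 0)
})
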