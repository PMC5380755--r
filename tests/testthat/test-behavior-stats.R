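test_that("rmssd and heart rate match brute-force recomputation", {
  expect_equal(rmssd(c(800, 810, 790, 810)),
               sqrt((10^2 + 20^2 + 20^2) / 3), tolerance = 1e-12)
  expect_equal(heart_rate(rep(800, 10)), 75)
  expect_equal(rmssd(rep(800, 10)), 0)
  set.seed(11)
  for (i in 1:100) {
    rr <- runif(sample(5:50, 1), 500, 1200)
    d <- rr[-1] - rr[-length(rr)]
    expect_equal(rmssd(rr), sqrt(sum(d^2) / length(d)), tolerance = 1e-12)
    expect_equal(heart_rate(rr), 60000 / mean(rr), tolerance = 1e-12)
  }
})

test_that("trial parameters from constructed streams hit their closed forms", {
  d <- generate_design(n_levels = 1, trials_per_level = 3, repetitions = 1,
                       speed_grid = 100, seed = 1L)
  fs <- 10
  t <- seq(0, d$duration, by = 1 / fs)
  streams <- data.frame(
    time = t,
    speed = 100,                       # exactly at target throughout
    brake = 0.2, throttle = 0.5,
    steering = 0, lane_offset = 0.1
  )
  rr <- rep(800, ceiling(d$duration / 0.8) + 2)
  tp <- compute_trial_params(streams, rr, d)
  expect_equal(tp$time_in_correct_range, rep(100, 3))
  expect_equal(tp$reaction_time, rep(0, 3), tolerance = 1e-9)
  expect_true(all(tp$correct))
  expect_equal(tp$brake_variance, rep(0, 3))
  expect_equal(tp$lane_deviation, rep(0.1, 3))
  expect_equal(tp$heart_rate, rep(75, 3))
  expect_equal(tp$rmssd, rep(0, 3))
})

test_that("reaction time requires entering and holding the speed band", {
  d <- generate_design(n_levels = 1, trials_per_level = 1, repetitions = 1,
                       speed_grid = 100, seed = 1L)
  fs <- 10
  t <- seq(0, d$duration, by = 1 / fs)
  onset <- d$trials$sign_onset[1]
  # reaches the band 4 s after the sign and stays
  sp <- ifelse(t < onset + 4, 80, 100)
  tp <- compute_trial_params(data.frame(time = t, speed = sp), NULL, d)
  expect_true(tp$correct)
  expect_equal(tp$reaction_time, 4, tolerance = 0.11)
  # dips out of the band near the end: incorrect, RT missing
  sp2 <- sp
  sp2[t > onset + 18] <- 70
  tp2 <- compute_trial_params(data.frame(time = t, speed = sp2), NULL, d)
  expect_false(tp2$correct)
  expect_true(is.na(tp2$reaction_time))
  # time in range excludes the 3 s transition: 14/17 of evaluated time in band
  expect_equal(tp2$time_in_correct_range, 100 * 14 / 17, tolerance = 1.5)
})

test_that("lane-change samples are excluded from lane deviation", {
  d <- generate_design(n_levels = 1, trials_per_level = 1, repetitions = 1,
                       speed_grid = 100, seed = 1L)
  t <- seq(0, d$duration, by = 0.1)
  onset <- d$trials$sign_onset[1]
  lane <- rep(0.2, length(t))
  lane[t > onset + 8 & t < onset + 12] <- 3.2   # crossing to another lane
  tp <- compute_trial_params(
    data.frame(time = t, speed = 100, lane_offset = lane), NULL, d)
  expect_equal(tp$lane_deviation, 0.2)
})

test_that("outlier screening removes only extreme trials and is idempotent", {
  set.seed(2)
  n <- 100
  tab <- tibble::tibble(
    participant_id = 1L, trial_index = 1:n, nback_level = rep(0:4, 20),
    target_speed = 100, heart_rate = rnorm(n, 75, 3)
  )
  tab$heart_rate[17] <- 75 + 5 * 3   # 5 SDs out
  r <- remove_outliers(tab, parameters = "heart_rate")
  expect_true(is.na(r$trials$heart_rate[17]))
  expect_equal(r$log$n_removed, 1L)
  expect_equal(r$log$fraction, 1 / 100)
  r2 <- remove_outliers(r$trials, parameters = "heart_rate")
  expect_identical(r2$trials$heart_rate, r$trials$heart_rate)
  # all-equal values: nothing removed, zero-SD handled
  tab2 <- tab
  tab2$heart_rate <- 75
  r3 <- remove_outliers(tab2, parameters = "heart_rate")
  expect_equal(r3$log$n_removed, 0L)
})

test_that("effect-size formula is monotone in df and hits its closed forms", {
  eff <- function(t, df) sqrt(t^2 / (t^2 + df))
  expect_equal(eff(2, 96), 0.2)
  dfs <- c(1e-6, 1, 10, 100, 1e4, 1e8)
  vals <- eff(2, dfs)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1, tolerance = 1e-6)
  expect_lt(vals[length(vals)], 1e-3)
})

test_that("mixed-model trend recovers slopes and matches OLS on balanced noiseless data", {
  d <- small_design(seed = 3L)
  p <- subject_params()
  p$table$between_sd[] <- 0
  p$table$resid_sd[] <- 0
  p$correct_prob <- rep(1, 5)
  b <- generate_behavior(d, p, n_participants = 3, seed = 4L)
  r <- suppressWarnings(lmm_trend(b, "heart_rate"))
  ols <- coef(lm(heart_rate ~ nback_level, data = b))[["nback_level"]]
  expect_equal(r$slope, ols, tolerance = 1e-6)
  expect_equal(r$slope, 0.89, tolerance = 1e-6)
  expect_equal(sign(r$effect_r), 1)
  rn <- suppressWarnings(lmm_trend(b, "rmssd"))
  expect_equal(rn$slope, -1.24, tolerance = 1e-6)
  expect_lt(rn$effect_r, 0)
})

test_that("mixed-model trend on noisy multi-participant data is near the generating slope", {
  d <- generate_design(seed = 6L)
  b <- generate_behavior(d, n_participants = 8, seed = 6L)
  r <- suppressWarnings(lmm_trend(b, "heart_rate"))
  expect_equal(r$slope, 0.89, tolerance = 0.25)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$chi2, 0)
  expect_true(is.finite(r$df) && r$df > 0)
  expect_error(lmm_trend(b[b$participant_id == 1, ], "heart_rate"),
               "2 participants")
})

test_that("null-generated data gives approximately uniform LRT p-values", {
  d <- small_design(seed = 9L)
  p <- subject_params(slopes = c(heart_rate = 0))
  pvals <- numeric(120)
  for (i in seq_len(120)) {
    b <- generate_behavior(d, p, n_participants = 6, seed = 5000L + i)
    r <- suppressWarnings(lmm_trend(b, "heart_rate"))
    pvals[i] <- r$p_value
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})
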