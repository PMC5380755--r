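test_that("optical density conversion: zero for constant input, decade log, positive-input guard", {
  m <- matrix(5, 3, 10)
  od <- intensity_to_od(list("760" = m, "850" = m))
  expect_true(all(od$od[["760"]] == 0))
  m2 <- m
  m2[2, 4] <- 0.5   # one decade below its mean would need ref = 5
  od2 <- intensity_to_od(list("760" = m2), reference = list("760" = 5))
  expect_equal(od2$od[["760"]][2, 4], 1)
  m3 <- m
  m3[1, 2] <- -1
  expect_error(intensity_to_od(list("760" = m3)), "channel 1, sample 2")
})

test_that("Beer-Lambert inversion recovers known concentrations through the forward relation", {
  cons <- beer_lambert_constants(distance_cm = 3.5)
  hbo <- matrix(1e-6, 1, 5)     # 1 uM
  hbr <- matrix(-0.5e-6, 1, 5)  # -0.5 uM
  base <- c("760" = 100, "850" = 100)
  raw <- mbll_forward(hbo, hbr, cons, base)
  od <- intensity_to_od(raw, reference = as.list(base))
  hemo <- mbll_convert(od, cons)
  expect_equal(hemo$hbo, hbo, tolerance = 1e-9)
  expect_equal(hemo$hbr, hbr, tolerance = 1e-9)
  # all-zero od maps to zero concentrations
  od0 <- intensity_to_od(list("760" = matrix(7, 2, 4),
                              "850" = matrix(7, 2, 4)))
  h0 <- mbll_convert(od0, beer_lambert_constants(distance_cm = c(3, 3.5)))
  expect_true(all(h0$hbo == 0) && all(h0$hbr == 0))
})

test_that("default constants carry the printed extinction and path-length values", {
  cons <- beer_lambert_constants()
  expect_equal(unname(cons$epsilon[1, ]), c(1486.59, 3843.71))
  expect_equal(unname(cons$epsilon[2, ]), c(2526.39, 1798.64))
  expect_equal(cons$dpf, c(7.25, 6.38))
  expect_error(beer_lambert_constants(epsilon = matrix(1, 2, 2)), "singular")
})

test_that("forward-generated recording round-trips through the inverse to the truth", {
  rec <- small_recording(seed = 9L)
  cons <- beer_lambert_constants(distance_cm = rec$montage$distance_cm)
  od <- intensity_to_od(rec$raw_intensity,
                        reference = as.list(rec$config$baseline_intensity))
  hemo <- mbll_convert(od, cons)
  rel <- max(abs(hemo$hbr - rec$truth_hbr)) / max(abs(rec$truth_hbr))
  expect_lt(rel, 1e-9)
  rel_o <- max(abs(hemo$hbo - rec$truth_hbo)) / max(abs(rec$truth_hbo))
  expect_lt(rel_o, 1e-9)
  # session-mean reference recovers the truth up to a per-channel constant
  hemo_m <- mbll_convert(intensity_to_od(rec$raw_intensity), cons)
  dm <- function(m) m - rowMeans(m)
  expect_lt(max(abs(dm(hemo_m$hbr) - dm(rec$truth_hbr))) /
              max(abs(rec$truth_hbr)), 1e-9)
})

test_that("FIR low-pass: unit DC gain, passband preserved, stopband attenuated, aligned", {
  h <- fir_ls_lowpass(77, 0.1, 1.955)
  expect_equal(sum(h), 1, tolerance = 1e-3)
  fs <- 1.955
  t <- (0:2999) / fs
  const <- lowpass_filter(rep(2.5, length(t)), 0.1, fs)
  expect_equal(const[100:2900], rep(2.5, 2801), tolerance = 1e-9)
  gain_at <- function(f0) {
    x <- sin(2 * pi * f0 * t)
    y <- lowpass_filter(x, 0.1, fs)
    core <- 200:2800
    sqrt(mean(y[core]^2) / mean(x[core]^2))
  }
  expect_gt(gain_at(0.05), 0.95)
  expect_lt(20 * log10(gain_at(0.5)), -20)
  # group delay compensated: slow sinusoid stays in phase
  x <- sin(2 * pi * 0.02 * t)
  y <- lowpass_filter(x, 0.1, fs)
  expect_gt(cor(x[200:2800], y[200:2800]), 0.9999)
  expect_error(lowpass_filter(x, 1.0, fs), "Nyquist")
})

test_that("filtering commutes with epoching on interior samples", {
  rec <- small_recording(seed = 4L)
  x <- rec$truth_hbr[1:3, ]
  whole <- lowpass_filter(x, 0.1, rec$sampling_rate)
  seg <- 301:900
  m <- (77 - 1) / 2
  inner <- (m + 1):(length(seg) - m)
  piece <- lowpass_filter(x[, seg, drop = FALSE], 0.1, rec$sampling_rate)
  expect_equal(piece[, inner], whole[, seg[inner]], tolerance = 1e-6)
})

test_that("channel QC implements the CV formula, either-wavelength rule and scale invariance", {
  set.seed(1)
  base <- matrix(rnorm(5 * 400, 100, 2), 5, 400)    # CV ~2%
  m1 <- base
  m1[2, ] <- rnorm(400, 100, 25)                    # CV ~25% at wavelength 1
  m2 <- base
  m2[4, ] <- rnorm(400, 100, 30)                    # CV ~30% at wavelength 2
  qc <- channel_qc(list("760" = m1, "850" = m2), threshold = 20)
  expect_setequal(qc$rejected_ids, c(2L, 4L))
  # formula check against direct computation
  expect_equal(unname(qc$cv_percent[1, "760"]),
               sd(m1[1, ]) / mean(m1[1, ]) * 100)
  # constant channel: CV 0, retained
  mc <- base
  mc[3, ] <- 42
  qc2 <- channel_qc(list("760" = mc), threshold = 20)
  expect_equal(unname(qc2$cv_percent[3, 1]), 0)
  expect_false(3L %in% qc2$rejected_ids)
  # zero-mean channel flagged with infinite CV, no error
  mz <- base
  mz[5, ] <- 0
  qc3 <- channel_qc(list("760" = mz))
  expect_true(is.infinite(qc3$cv_percent[5, 1]))
  expect_true(5L %in% qc3$rejected_ids)
  # scale invariance
  scaled <- base
  scaled[1, ] <- scaled[1, ] * 37.5
  expect_equal(channel_qc(list(a = scaled))$cv_percent[1, 1],
               channel_qc(list(a = base))$cv_percent[1, 1])
})

test_that("bad channels injected by the generator are exactly the ones rejected", {
  d <- small_design()
  cfg <- forward_model_config(seed = 3L, bad_channel_ids = c(13L, 55L))
  rec <- generate_fnirs(d, cfg)
  qc <- channel_qc(rec$raw_intensity, threshold = 20)
  expect_setequal(qc$rejected_ids, c(13L, 55L))
})

test_that("sample labeling, transition exclusion and incorrect-trial removal", {
  d <- small_design()
  rec <- small_recording(design = d)
  cons <- beer_lambert_constants(distance_cm = rec$montage$distance_cm)
  hemo <- mbll_convert(intensity_to_od(rec$raw_intensity), cons,
                       sampling_rate = rec$sampling_rate,
                       montage = rec$montage)
  # no exclusion: every in-trial sample retained
  ss0 <- build_sample_set(hemo, d, transition_exclusion = 0,
                          drop_incorrect = FALSE)
  expect_true(all(ss0$excluded$reason == "outside_trial"))
  n_in_trial <- sum(!is.na(induced_level_trace(d, (seq_along(rec$time) - 1) /
                                                 rec$sampling_rate)))
  expect_equal(nrow(ss0$features), n_in_trial)
  # +-3 s exclusion leaves ~ (20 - 6) * fs ~ 27 samples for trials followed
  # by another sign; block-final trials lose only the leading 3 s
  ss3 <- build_sample_set(hemo, d, transition_exclusion = 3)
  counts <- table(ss3$trial_id)
  interior <- d$trials$index[-cumsum(rle(d$trials$block_id)$lengths)]
  expect_true(all(counts[as.character(interior)] %in% 27:28))
  per_trial <- nrow(ss3$features) / nrow(d$trials)
  expect_gt(per_trial, 26)
  expect_lt(per_trial, 31)
  expect_true(all(ss3$labels %in% 0:4))
  # one incorrect trial drops exactly its samples
  d_bad <- d
  d_bad$trials$correct[5] <- FALSE
  ss_bad <- build_sample_set(hemo, d_bad, transition_exclusion = 3)
  expect_false(5 %in% ss_bad$trial_id)
  expect_equal(sum(ss3$trial_id == 5),
               sum(ss_bad$excluded$reason == "incorrect_trial"))
  expect_equal(nrow(ss3$features) - sum(ss3$trial_id == 5),
               nrow(ss_bad$features))
})

test_that("sample-set features permute with channel order and labels are design-determined", {
  d <- small_design()
  rec <- small_recording(design = d)
  cons <- beer_lambert_constants(distance_cm = rec$montage$distance_cm)
  hemo <- mbll_convert(intensity_to_od(rec$raw_intensity), cons,
                       sampling_rate = rec$sampling_rate,
                       montage = rec$montage)
  ss <- build_sample_set(hemo, d)
  perm <- sample(nrow(hemo$hbr))
  hemo_p <- hemo
  hemo_p$hbr <- hemo$hbr[perm, ]
  hemo_p$montage <- hemo$montage[perm, ]
  ss_p <- build_sample_set(hemo_p, d)
  expect_identical(ss$labels, ss_p$labels)
  expect_equal(ss_p$features, ss$features[, perm], ignore_attr = TRUE)
})
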