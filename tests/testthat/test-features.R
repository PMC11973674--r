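test_that("peak_to_peak is max minus min", {
  expect_equal(peak_to_peak(c(1, -2, 3)), 5)
  expect_equal(peak_to_peak(rep(4, 10)), 0)
  a <- 1.7
  s <- a * sin(2 * pi * seq(0, 1, length.out = 1001))
  expect_equal(peak_to_peak(s), 2 * a, tolerance = 1e-4)
  expect_error(peak_to_peak(numeric(0)))
})

test_that("segment features are medians over clean beats only", {
  x <- numeric(3000)
  # three beats with peak-to-peak 1, 2, 3 inside their windows
  w <- extract_atrial_windows(c(500L, 1500L, 2500L), 1000, 3000)
  x[w$start[1] + 10] <- 1
  x[w$start[2] + 10] <- 2
  x[w$start[3] + 10] <- 3
  seg <- tibble::tibble(segment = 1L, start = 1L, end = 3001L,
                        beats = list(1:3))
  expect_equal(segment_feature(seg, x, w), 2)
  # contaminated beat is ignored
  w$contaminated[3] <- TRUE
  expect_equal(segment_feature(seg, x, w), 1.5)
  # single clean beat: its own value
  w$contaminated[2:3] <- TRUE
  expect_equal(segment_feature(seg, x, w), 1)
  # nothing clean: undefined
  w$contaminated[1:3] <- TRUE
  expect_true(is.na(segment_feature(seg, x, w)))
})

test_that("feature grid has two baseline points and starts LF at +30 s", {
  f <- test_features("PFA_T-", seed = 7, post_s = 200, noise_sd = 0)
  for (band in unique(f$channel_band)) {
    fb <- f[f$channel_band == band, ]
    expect_equal(sum(fb$t_rel_s < 0), 2)
    expect_equal(fb$t_rel_s[1:2], c(-15, -5))
  }
  lf <- f[f$channel_band == "unipolar_LF" & f$t_rel_s > 0 & f$valid, ]
  expect_equal(min(lf$t_rel_s), 35)     # centre of the [30, 40) s segment
  hf <- f[f$channel_band == "bipolar_HF" & f$t_rel_s > 0 & f$valid, ]
  expect_equal(min(hf$t_rel_s), 5)      # bipolar valid immediately
})

test_that("SHAM feature series stay flat within noise", {
  f <- test_features("SHAM", seed = 8, post_s = 120, noise_sd = 0.05)
  for (band in c("bipolar_HF", "unipolar_LF")) {
    v <- f$value_mV[f$channel_band == band & f$valid]
    expect_lt(diff(range(v)) / stats::median(v), 0.25)
  }
})

test_that("normalization fixes the reference at 1 and is scale invariant", {
  f <- test_features("PFA_T-", seed = 7, post_s = 200, noise_sd = 0)
  lf <- normalize_series(f[f$channel_band == "unipolar_LF", ], "post30s")
  expect_equal(lf$normalized[lf$t_rel_s == 35], 1)
  hf <- normalize_series(f[f$channel_band == "bipolar_HF", ],
                         "preablation")
  expect_equal(hf$normalized[hf$t_rel_s == -5], 1)
  hf_first <- normalize_series(f[f$channel_band == "bipolar_HF", ],
                               "preablation", pre_reference = "first")
  expect_equal(hf_first$normalized[hf_first$t_rel_s == -15], 1)
  # doubling the raw values changes nothing after normalization
  f2 <- f
  f2$value_mV <- f2$value_mV * 2
  lf2 <- normalize_series(f2[f2$channel_band == "unipolar_LF", ], "post30s")
  expect_equal(lf2$normalized, lf$normalized)
})

test_that("noise-free series recover the generating trajectories", {
  for (grp in c("PFA_T-", "PFA_T+")) {
    f <- test_features(grp, seed = 7, post_s = 200, noise_sd = 0)
    dyn <- group_dynamics(grp)
    hf <- normalize_series(f[f$channel_band == "bipolar_HF", ],
                           "preablation")
    hf <- hf[hf$valid, ]
    expect_lt(max(abs(hf$normalized -
                        hf_survival_trajectory(hf$t_rel_s, dyn$hf)) /
                    hf_survival_trajectory(hf$t_rel_s, dyn$hf)), 0.1)
    lf <- normalize_series(f[f$channel_band == "unipolar_LF", ], "post30s")
    lf <- lf[lf$valid & lf$t_rel_s > 0, ]
    ref <- coi_trajectory(lf$t_rel_s[1], dyn$coi)
    expected <- coi_trajectory(lf$t_rel_s, dyn$coi) / ref
    expect_lt(max(abs(lf$normalized - expected) / expected), 0.1)
  }
})

test_that("excluded segments appear as gaps, not zeros", {
  rec <- test_record("RFA_T+", seed = 44, post_s = 120, noise_sd = 0.05)
  bad <- inject_artifacts(rec, rate = 0.5, amplitude_mV = 15,
                          duration_ms = 400, seed = 3)
  f <- build_feature_series(bad)
  hf <- f[f$channel_band == "bipolar_HF", ]
  expect_gt(sum(!hf$valid), 0)
  expect_true(all(is.na(hf$value_mV[!hf$valid])))
  expect_false(any(hf$value_mV[hf$valid] == 0, na.rm = TRUE))
})
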