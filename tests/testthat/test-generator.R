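test_that("generation is deterministic given a seed", {
  cfg <- generator_config(duration_post_s = 60)
  a <- generate_lesion_recording(cfg, "PFA_T+", seed = 5)
  b <- generate_lesion_recording(cfg, "PFA_T+", seed = 5)
  expect_identical(a$signals, b$signals)
  expect_identical(a$truth$r_peak_indices, b$truth$r_peak_indices)
  c <- generate_lesion_recording(cfg, "PFA_T+", seed = 6)
  expect_false(identical(a$signals$ecg, c$signals$ecg))
})

test_that("PFA recordings rail the unipolar channel for 30 s", {
  rec <- test_record("PFA_T+", seed = 5, post_s = 60, noise_sd = 0.05)
  abl <- rec$ablation_index
  sat <- rec$truth$saturation_interval
  expect_equal(sat[1], abl)
  expect_equal(sat[2], abl + 30 * rec$fs - 1)
  expect_true(all(rec$signals$unipolar[sat[1]:sat[2]] == rec$meta$rail_mV))
  # RFA: no saturation
  rfa <- test_record("RFA_T+", seed = 5, post_s = 60, noise_sd = 0.05)
  expect_null(rfa$truth$saturation_interval)
})

test_that("beat templates separate spectrally as designed", {
  fs <- 1000
  energy_above <- function(x, f_cut) {
    n <- 4096
    xp <- c(x, numeric(n - length(x)))
    p <- Mod(fft(xp))^2
    f <- (seq_len(n) - 1) * fs / n
    half <- f <= fs / 2
    sum(p[half & f >= f_cut]) / sum(p[half])
  }
  spike <- coiwave:::.biphasic_template(4, fs)
  expect_gt(energy_above(spike, 63), 0.8)
  plateau <- coiwave:::.plateau_template(100, fs)
  in_lf <- function(x) {
    n <- 4096
    xp <- c(x, numeric(n - length(x)))
    p <- Mod(fft(xp))^2
    f <- (seq_len(n) - 1) * fs / n
    half <- f <= fs / 2
    sum(p[half & f >= 1 & f <= 16]) / sum(p[half & f >= 1])
  }
  # excluding DC (the plateau rides on each beat, so its repetition-rate
  # content is what the LF band sees)
  expect_gt(in_lf(plateau), 0.8)
})

test_that("default cohort matches the study design", {
  cfg <- generator_config(duration_post_s = 40)
  coh <- generate_cohort(cfg, seed = 9)
  expect_length(coh$records, 38)
  expect_equal(nrow(coh$manifest), 38)
  expect_equal(length(unique(coh$manifest$animal_id)), 5)
  expect_equal(sum(coh$manifest$modality == "PFA"), 21)
  expect_equal(sum(coh$manifest$modality == "RFA"), 17)
  # reproducible labels and per-lesion seeds
  coh2 <- generate_cohort(cfg, seed = 9)
  expect_identical(coh$manifest, coh2$manifest)
  # empty cohort
  empty <- generate_cohort(cfg, n_pfa_trans = 0, n_pfa_nontrans = 0,
                           n_rfa_trans = 0, n_rfa_nontrans = 0, seed = 1)
  expect_length(empty$records, 0)
})

test_that("artifact injection flags exactly the corrupted beats", {
  rec <- test_record("RFA_T+", seed = 12, post_s = 60, noise_sd = 0.05)
  same <- inject_artifacts(rec, rate = 0)
  expect_identical(same$signals, rec$signals)

  bad <- inject_artifacts(rec, rate = 0.3, seed = 4)
  hit <- bad$truth$contaminated_beat_indices
  expect_gt(length(hit), 0)
  # flagging recovers the injected beats (recall >= 0.9)
  w <- extract_atrial_windows(bad$truth$r_peak_indices, bad$fs,
                              nrow(bad$signals))
  w <- flag_contaminated_beats(bad, w, "bipolar")
  recall <- mean(hit %in% w$beat[w$contaminated])
  expect_gte(recall, 0.9)
  # clean beats mostly stay clean
  clean <- setdiff(w$beat[w$in_bounds], hit)
  expect_lt(mean(clean %in% w$beat[w$contaminated]), 0.1)
})
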