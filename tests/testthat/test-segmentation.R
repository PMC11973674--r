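test_that("atrial windows span [r - 200 ms, r - 50 ms)", {
  w <- extract_atrial_windows(c(1000L, 2000L), fs = 1000,
                              record_length = 5000)
  expect_equal(w$start[1], 800L)
  expect_equal(w$end[1], 950L)
  expect_equal(w$end[1] - w$start[1], 150L)
  expect_true(all(w$in_bounds))
  # a peak too early leaves the record: out of bounds
  w2 <- extract_atrial_windows(100L, fs = 1000, record_length = 5000)
  expect_false(w2$in_bounds[1])
  expect_equal(nrow(extract_atrial_windows(integer(0), 1000, 5000)), 0)
})

test_that("segments tile the record without overlap, ablation on an edge", {
  rec <- test_record("RFA_T+", seed = 41, post_s = 600, noise_sd = 0.05)
  w <- extract_atrial_windows(rec$truth$r_peak_indices, rec$fs,
                              nrow(rec$signals))
  seg <- segment_record(rec, w)
  expect_equal(nrow(seg), 63)                       # 3 pre + 60 post
  expect_equal(sum(seg$t_center_rel_s < 0), 3)
  expect_true(all(diff(seg$start) == 10000))
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # disjoint, contiguous
  expect_true(any(seg$start == rec$ablation_index)) # boundary at ablation
  # every in-bounds beat lands in exactly one segment
  ids <- sort(unlist(seg$beats))
  expect_identical(ids, w$beat[w$in_bounds &
                                 w$r_peak_index >= min(seg$start) &
                                 w$r_peak_index < max(seg$end)])
})

test_that("a beat exactly on a segment boundary joins the later segment", {
  rec <- test_record("RFA_T+", seed = 41, post_s = 600, noise_sd = 0.05)
  w <- extract_atrial_windows(c(rec$ablation_index), rec$fs,
                              nrow(rec$signals))
  seg <- segment_record(rec, w)
  holder <- seg[vapply(seg$beats, function(b) 1 %in% b, logical(1)), ]
  expect_equal(holder$start, rec$ablation_index)
  expect_equal(holder$t_start_rel_s, 0)
})

test_that("the 20% contamination rule excludes strictly above the limit", {
  base <- tibble::tibble(
    segment = 1:3, start = c(1, 10001, 20001), end = c(10001, 20001, 30001),
    t_start_rel_s = c(-10, 0, 10), t_center_rel_s = c(-5, 5, 15),
    n_beats = 10L, n_contaminated = c(2L, 3L, 0L),
    contaminated_fraction = c(0.2, 0.3, 0),
    beats = list(1:10, 11:20, 21:30)
  )
  out <- apply_exclusion_rules(base)
  expect_true(out$valid_bipolar[1])    # exactly 20%: retained
  expect_false(out$valid_bipolar[2])   # 30%: excluded
  expect_true(out$valid_bipolar[3])
  # unipolar additionally blanked on [0, 30) s post-ablation
  expect_false(out$valid_unipolar[2])
  expect_false(out$valid_unipolar[3])
  expect_true(out$valid_unipolar[1])
  # empty segments are invalid
  base$n_beats[3] <- 0L; base$contaminated_fraction[3] <- NA_real_
  expect_false(apply_exclusion_rules(base)$valid_bipolar[3])
})

test_that("adding contaminated beats never revalidates a segment", {
  seg <- tibble::tibble(
    segment = 1L, start = 1, end = 10001, t_start_rel_s = 10,
    t_center_rel_s = 15, n_beats = 10L, n_contaminated = 0L,
    contaminated_fraction = 0, beats = list(1:10)
  )
  was_valid <- TRUE
  for (k in 0:10) {
    seg$n_contaminated <- k
    seg$contaminated_fraction <- k / 10
    v <- apply_exclusion_rules(seg)$valid_bipolar
    expect_true(was_valid || !v)   # once invalid, stays invalid
    was_valid <- v
  }
})

test_that("saturated windows are flagged as contaminated", {
  rec <- test_record("PFA_T+", seed = 42, post_s = 60, noise_sd = 0.05)
  w <- extract_atrial_windows(rec$truth$r_peak_indices, rec$fs,
                              nrow(rec$signals))
  w <- flag_contaminated_beats(rec, w, "unipolar")
  sat <- rec$truth$saturation_interval
  inside <- w$r_peak_index > sat[1] + 250 & w$r_peak_index <= sat[2]
  expect_true(all(w$contaminated[inside]))
  before <- w$in_bounds & w$end <= sat[1]
  expect_false(any(w$contaminated[before]))
})
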