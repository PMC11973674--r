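# Minimal feature table builder for classifier tests: one unipolar_LF row
# per lesion per timepoint, already normalized.
lf_table <- function(scores_by_lesion, transmural, t_grid = c(35, 45, 55, 65),
                     modality = "PFA") {
  purrr::imap(scores_by_lesion, function(vals, i) {
    tibble::tibble(
      lesion_id = sprintf("L%02d", as.integer(i)),
      animal_id = "A1", modality = modality,
      transmural = transmural[as.integer(i)],
      group = paste0(modality, ifelse(transmural[as.integer(i)],
                                      "_T+", "_T-")),
      channel_band = "unipolar_LF", segment = seq_along(t_grid),
      t_rel_s = t_grid, n_beats = 10L, contaminated_fraction = 0,
      valid = TRUE, value_mV = vals, normalized = vals,
      normalization_mode = "post30s"
    )
  }) |> dplyr::bind_rows()
}

test_that("scores pick the valid segment nearest the decision time", {
  tab <- lf_table(list(`1` = c(1, 0.9, 0.8, 0.7)), transmural = TRUE)
  sc <- transmurality_scores(tab, decision_time_s = 60)
  # 55 and 65 are equidistant from 60: the later segment wins
  expect_equal(sc$score_time_s, 65)
  expect_equal(sc$score, 0.7)
  sc55 <- transmurality_scores(tab, decision_time_s = 55)
  expect_equal(sc55$score, 0.8)
})

test_that("RFA and SHAM inputs are refused", {
  tab <- lf_table(list(`1` = c(1, 0.9, 0.8, 0.7)), TRUE,
                  modality = "RFA")
  expect_error(transmurality_scores(tab), "RFA")
  tab$modality <- "SHAM"
  expect_error(transmurality_scores(tab), "SHAM")
})

test_that("threshold calibration maximizes Youden's J", {
  # perfectly separated: midpoint of the gap
  th <- calibrate_threshold(c(0.2, 0.3, 0.8, 0.9),
                            c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(th, 0.55)
  # indistinguishable distributions: pooled median
  s <- c(1, 2, 3, 4)
  th2 <- calibrate_threshold(c(s, s), rep(c(TRUE, FALSE), each = 4))
  expect_equal(th2, stats::median(c(s, s)))
})

test_that("a score at the threshold is called transmural (tie-break)", {
  tab <- lf_table(list(`1` = c(1, 0.9, 0.8, 0.75),
                       `2` = c(1, 0.8, 0.6, 0.40)),
                  transmural = c(TRUE, FALSE))
  calls <- predict_transmurality(tab, threshold = 0.75)
  expect_equal(calls$label[calls$score == 0.75], "transmural")
  expect_equal(calls$label[calls$score == 0.40], "nontransmural")
  expect_true(all(calls$correct))
})

test_that("lowering a score never flips nontransmural to transmural", {
  t_grid <- c(35, 45, 55, 65)
  th <- 0.7
  for (v in seq(1, 0, by = -0.05)) {
    tab <- lf_table(list(`1` = c(1, 1, 1, v)), transmural = TRUE)
    lab <- predict_transmurality(tab, threshold = th)$label
    if (v >= th) expect_equal(lab, "transmural")
    else expect_equal(lab, "nontransmural")
  }
})

test_that("slope mode scores order the groups the same way", {
  fast <- lf_table(list(`1` = c(1, 0.75, 0.55, 0.4)), FALSE)  # fast recovery
  slow <- lf_table(list(`1` = c(1, 0.95, 0.9, 0.87)), TRUE)
  s_fast <- transmurality_scores(fast, mode = "slope")$score
  s_slow <- transmurality_scores(slow, mode = "slope")$score
  expect_lt(s_fast, s_slow)   # more negative slope for nontransmural
})
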