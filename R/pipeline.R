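# End-to-end cohort pipeline: simulate (or load) recordings, extract and
# normalize feature series, run group statistics, and call transmurality.
# Record I/O is plain CSV plus a JSON sidecar so every artifact is
# inspectable and reproducible from config + seed.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] used when simulating.
#' @param cohort Named list of group sizes passed to [generate_cohort()]
#'   (`n_pfa_trans`, `n_pfa_nontrans`, `n_rfa_trans`, `n_rfa_nontrans`,
#'   `n_animals`, `animal_sd`).
#' @param qrs A [qrs_params()].
#' @param pre_reference Pre-ablation normalization reference for the HF
#'   series: `"last"` (default) or `"first"` baseline point.
#' @param stats_interval Two seconds: LME/slope interval (default 30-180).
#' @param decision_time_s Transmurality decision time (default 60).
#' @param seed Master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            cohort = list(),
                            qrs = qrs_params(),
                            pre_reference = "last",
                            stats_interval = c(30, 180),
                            decision_time_s = 60,
                            seed = 1L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(qrs, "qrs_params"),
            length(stats_interval) == 2,
            stats_interval[1] < stats_interval[2],
            decision_time_s >= 30)
  structure(list(generator = generator, cohort = cohort, qrs = qrs,
                 pre_reference = pre_reference,
                 stats_interval = stats_interval,
                 decision_time_s = decision_time_s, seed = seed),
            class = "pipeline_config")
}

#' Extract normalized feature tables for a list of records
#'
#' Convenience wrapper running [build_feature_series()] on each record and
#' applying the two normalization conventions: `bipolar_HF` (and
#' `bipolar_raw`) to the pre-ablation reference, `unipolar_LF` (and
#' `unipolar_raw`) to the first valid post-ablation value.
#'
#' @param records List of `lesion_record` objects.
#' @param qrs A [qrs_params()].
#' @param pre_reference `"last"` or `"first"` pre-ablation point.
#' @return Feature tibble with `normalized` column.
#' @export
cohort_features <- function(records, qrs = qrs_params(),
                            pre_reference = "last") {
  feats <- purrr::map(records, build_feature_series, qrs = qrs) |>
    dplyr::bind_rows()
  bip <- feats |>
    dplyr::filter(grepl("^bipolar", .data$channel_band)) |>
    normalize_series(mode = "preablation", pre_reference = pre_reference)
  uni <- feats |>
    dplyr::filter(grepl("^unipolar", .data$channel_band)) |>
    normalize_series(mode = "post30s")
  dplyr::bind_rows(bip, uni) |>
    dplyr::arrange(.data$lesion_id, .data$channel_band, .data$t_rel_s)
}

# one LME comparison, tolerating failure (e.g. too few animals)
.try_lme <- function(d, interval) {
  tryCatch(
    fit_lme(d, t_from_s = interval[1], t_to_s = interval[2]),
    error = function(e) NULL
  )
}

#' Run the full cohort pipeline
#'
#' Simulates a cohort, extracts normalized feature series, and runs the
#' group analyses: mixed-effects models (with time-by-group ANOVA) for the
#' PFA transmural-vs-nontransmural and PFA-vs-RFA comparisons on the
#' bipolar HF and unipolar LF bands; per-timepoint two-group tests;
#' per-lesion recovery slopes on the stats interval; and transmurality
#' calls on the PFA lesions with a cohort-calibrated threshold.
#'
#' @param config A [pipeline_config()].
#' @param records Optional list of `lesion_record`s to analyse instead of
#'   simulating (e.g. from [read_record()]).
#' @return Object of class `"cohort_result"`: list with `features`,
#'   `manifest`, `lme` (tibble of comparisons), `timepoint_tests`,
#'   `slopes`, `calls`, `threshold`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(records)) {
    cohort <- do.call(generate_cohort,
                      c(list(cfg = config$generator, seed = config$seed),
                        config$cohort))
    records <- cohort$records
    manifest <- cohort$manifest
  } else {
    manifest <- purrr::map(records, function(r) {
      tibble::as_tibble(r$meta[c("lesion_id", "animal_id", "modality",
                                 "transmural", "group")])
    }) |> dplyr::bind_rows()
  }
  if (length(records) == 0) stop("empty cohort", call. = FALSE)

  features <- cohort_features(records, qrs = config$qrs,
                              pre_reference = config$pre_reference)

  iv <- config$stats_interval
  comparisons <- list(
    list(name = "PFA_trans_vs_nontrans", band = "bipolar_HF",
         filter = function(f) dplyr::filter(f, .data$modality == "PFA"),
         grouping = "transmural"),
    list(name = "PFA_trans_vs_nontrans", band = "unipolar_LF",
         filter = function(f) dplyr::filter(f, .data$modality == "PFA"),
         grouping = "transmural"),
    list(name = "PFA_vs_RFA", band = "bipolar_HF",
         filter = identity, grouping = "modality"),
    list(name = "PFA_vs_RFA", band = "unipolar_LF",
         filter = identity, grouping = "modality")
  )
  lme_rows <- list()
  tp_rows <- list()
  for (cmp in comparisons) {
    d <- features |>
      dplyr::filter(.data$channel_band == cmp$band) |>
      cmp$filter()
    if (nrow(d) == 0 || length(unique(d[[cmp$grouping]])) < 2) next
    d$group_cmp <- as.character(d[[cmp$grouping]])
    fit <- .try_lme(dplyr::rename(d, group_orig = "group",
                                  group = "group_cmp"), iv)
    if (!is.null(fit)) {
      lme_rows[[length(lme_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(comparison = cmp$name, channel_band = cmp$band),
        glance(fit)
      )
    }
    tp <- compare_timepoints(
      dplyr::filter(d, .data$t_rel_s > 0), group_col = "group_cmp")
    if (nrow(tp) > 0) {
      tp_rows[[length(tp_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(comparison = cmp$name, channel_band = cmp$band)[
          rep(1, nrow(tp)), ], tp)
    }
  }

  slopes <- dplyr::bind_rows(
    recovery_slopes(dplyr::filter(features,
                                  .data$channel_band == "bipolar_HF"),
                    t_from_s = iv[1], t_to_s = iv[2]) |>
      dplyr::mutate(channel_band = "bipolar_HF"),
    recovery_slopes(dplyr::filter(features,
                                  .data$channel_band == "unipolar_LF"),
                    t_from_s = iv[1], t_to_s = iv[2]) |>
      dplyr::mutate(channel_band = "unipolar_LF")
  )

  calls <- NULL
  threshold <- NA_real_
  pfa_lf <- dplyr::filter(features, .data$modality == "PFA")
  if (nrow(pfa_lf) > 0 && length(unique(pfa_lf$transmural)) == 2) {
    sc <- transmurality_scores(pfa_lf, config$decision_time_s)
    threshold <- calibrate_threshold(sc$score, sc$transmural)
    calls <- predict_transmurality(pfa_lf, threshold,
                                   config$decision_time_s)
  }

  structure(
    list(features = features, manifest = manifest,
         lme = dplyr::bind_rows(lme_rows),
         timepoint_tests = dplyr::bind_rows(tp_rows),
         slopes = slopes, calls = calls, threshold = threshold,
         config = config),
    class = "cohort_result"
  )
}

#' @exportS3Method base::print
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", nrow(x$manifest), "lesions,",
      length(unique(x$manifest$animal_id)), "animals\n")
  if (nrow(x$lme) > 0) {
    cat("mixed-effects comparisons:\n")
    print(x$lme[, c("comparison", "channel_band", "p_time",
                    "p_interaction")])
  }
  if (!is.null(x$calls)) {
    cat(sprintf("transmurality calls (threshold %.3f): balanced accuracy %.2f\n",
                x$threshold, balanced_accuracy(x$calls)))
  }
  invisible(x)
}

#' Write a lesion recording to CSV + JSON sidecar
#'
#' The signal file is a long CSV (`sample`, `ecg`, `bipolar`, `unipolar`,
#' in mV); sampling frequency, ablation index, metadata and ground truth go
#' to `<path>.json`.
#'
#' @param record A `lesion_record`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "lesion_record"))
  readr::write_csv(record$signals, path)
  side <- list(
    fs = record$fs,
    ablation_index = record$ablation_index,
    meta = record$meta,
    truth = record$truth[c("r_peak_indices", "beat_atrial_indices",
                           "contaminated_beat_indices",
                           "saturation_interval")]
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a lesion recording written by [write_record()]
#'
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @param fs Optional expected sampling frequency; a mismatch with the
#'   sidecar is an error.
#' @return A `lesion_record` (ground-truth fields limited to what the
#'   sidecar carries).
#' @export
read_record <- function(path, fs = NULL) {
  signals <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample", "ecg", "bipolar", "unipolar")
  if (!all(need %in% names(signals))) {
    stop("signal file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(fs) && !isTRUE(all.equal(fs, side$fs))) {
    stop("sampling frequency mismatch: file says ", side$fs,
         " Hz, expected ", fs, call. = FALSE)
  }
  truth <- side$truth
  truth$r_peak_indices <- as.integer(truth$r_peak_indices)
  truth$beat_atrial_indices <- as.integer(truth$beat_atrial_indices)
  truth$contaminated_beat_indices <-
    as.integer(truth$contaminated_beat_indices)
  if (!is.null(truth$saturation_interval)) {
    truth$saturation_interval <- as.integer(truth$saturation_interval)
  }
  structure(
    list(signals = tibble::as_tibble(signals)[, need],
         fs = side$fs,
         ablation_index = as.integer(side$ablation_index),
         meta = side$meta,
         truth = truth),
    class = "lesion_record"
  )
}

#' Write cohort results to JSON
#'
#' Serializes the group-level outputs of [run_pipeline()] (LME table,
#' per-timepoint tests, slopes, calls, threshold, seed) to a JSON file.
#'
#' @param result A `cohort_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(result, path) {
  stopifnot(inherits(result, "cohort_result"))
  out <- list(
    seed = result$config$seed,
    n_lesions = nrow(result$manifest),
    lme = result$lme,
    timepoint_tests = result$timepoint_tests,
    slopes = result$slopes,
    threshold = result$threshold,
    calls = result$calls
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
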