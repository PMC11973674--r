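# Peak-to-peak amplitude features on raw and sub-band signals, aggregated
# per 10-second segment and normalized per lesion.

#' Peak-to-peak amplitude of a window
#'
#' @param window_samples Non-empty numeric vector.
#' @return `max - min`, in the units of the input (>= 0).
#' @export
peak_to_peak <- function(window_samples) {
  stopifnot(length(window_samples) > 0, all(is.finite(window_samples)))
  max(window_samples) - min(window_samples)
}

#' Median per-beat peak-to-peak value of one segment
#'
#' Computes the peak-to-peak amplitude of `band_signal` inside each
#' uncontaminated, in-bounds atrial window of the segment and returns the
#' median. `band_signal` is indexed in record coordinates.
#'
#' @param segment One row of a [segment_record()] tibble.
#' @param band_signal Numeric vector covering the segment's samples, in
#'   record coordinates (may be the full record or the segment slice, see
#'   `offset`).
#' @param windows Window tibble.
#' @param offset Index of `band_signal[1]` in record coordinates (default 1:
#'   full-record signal).
#' @return Median peak-to-peak value (mV), or `NA` if no clean beat.
#' @export
segment_feature <- function(segment, band_signal, windows, offset = 1L) {
  beats <- segment$beats[[1]]
  w <- windows[windows$beat %in% beats &
                 windows$in_bounds & !windows$contaminated, , drop = FALSE]
  if (nrow(w) == 0) return(NA_real_)
  pp <- vapply(seq_len(nrow(w)), function(i) {
    idx <- (w$start[i]:(w$end[i] - 1L)) - offset + 1L
    peak_to_peak(band_signal[idx])
  }, numeric(1))
  stats::median(pp)
}

# Valid analysis grid: the last two complete pre-ablation segments plus all
# post-ablation segments.
.grid_segments <- function(segments) {
  pre <- which(segments$t_center_rel_s < 0)
  if (length(pre) < 2) {
    stop("recording must contain at least 20 s (two complete 10-s segments) ",
         "of pre-ablation baseline", call. = FALSE)
  }
  c(pre[(length(pre) - 1):length(pre)], which(segments$t_center_rel_s > 0))
}

#' Build per-lesion feature time series
#'
#' Runs the full single-lesion pipeline on a recording: QRS detection,
#' atrial windowing, per-channel contamination flagging, 10-second
#' segmentation with exclusion rules, db6 sub-band reconstruction, and
#' median per-segment peak-to-peak features for four channel/band
#' combinations: `bipolar_raw`, `unipolar_raw`, `bipolar_HF` (63-500 Hz)
#' and `unipolar_LF` (1-16 Hz). The time grid has exactly two pre-ablation
#' points (the last two complete baseline segments) and one point per 10 s
#' after ablation; excluded segments yield `NA` values (gaps, never zeros).
#'
#' @param record A `lesion_record`.
#' @param qrs A [qrs_params()] object.
#' @param r_peaks Optional pre-computed R-peak indices (defaults to running
#'   the detector).
#' @return Tibble: `lesion_id`, `animal_id`, `modality`, `transmural`,
#'   `group`, `channel_band`, `segment`, `t_rel_s` (segment centre),
#'   `n_beats`, `contaminated_fraction`, `valid`, `value_mV`.
#' @export
build_feature_series <- function(record, qrs = qrs_params(),
                                 r_peaks = NULL) {
  stopifnot(inherits(record, "lesion_record"))
  fs <- record$fs
  n <- nrow(record$signals)
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(record, qrs)

  w0 <- extract_atrial_windows(r_peaks, fs, n)
  wins <- list(
    bipolar = flag_contaminated_beats(record, w0, "bipolar"),
    unipolar = flag_contaminated_beats(record, w0, "unipolar")
  )
  segs <- lapply(wins, function(w) {
    apply_exclusion_rules(segment_record(record, w))
  })

  bands <- list(
    bipolar_raw = list(channel = "bipolar", levels = NULL),
    unipolar_raw = list(channel = "unipolar", levels = NULL),
    bipolar_HF = list(channel = "bipolar", levels = band_preset("HF")),
    unipolar_LF = list(channel = "unipolar", levels = band_preset("LF"))
  )

  out <- purrr::imap(bands, function(bd, band_name) {
    ch <- bd$channel
    seg_tbl <- segs[[ch]]
    win_tbl <- wins[[ch]]
    valid_col <- if (ch == "bipolar") "valid_bipolar" else "valid_unipolar"
    keep <- .grid_segments(seg_tbl)
    x <- record$signals[[ch]]
    rows <- lapply(keep, function(i) {
      seg <- seg_tbl[i, ]
      valid <- seg[[valid_col]]
      value <- NA_real_
      if (isTRUE(valid)) {
        # atrial windows of early beats start up to 200 ms before the
        # segment, so the decomposed slice is extended left to cover them
        lo <- max(1L, seg$start - as.integer(round(0.200 * fs)))
        sl <- x[lo:(seg$end - 1L)]
        band_sig <- if (is.null(bd$levels)) sl else
          .dwt_band_signal(sl, bd$levels)
        value <- segment_feature(seg, band_sig, win_tbl, offset = lo)
        if (is.na(value)) valid <- FALSE
      }
      tibble::tibble(
        channel_band = band_name,
        segment = seg$segment,
        t_rel_s = seg$t_center_rel_s,
        n_beats = seg$n_beats,
        contaminated_fraction = seg$contaminated_fraction,
        valid = isTRUE(valid) & !is.na(value),
        value_mV = value
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_cols(
    tibble::tibble(
      lesion_id = record$meta$lesion_id,
      animal_id = record$meta$animal_id,
      modality = record$meta$modality,
      transmural = record$meta$transmural,
      group = record$meta$group
    )[rep(1, sum(vapply(out, nrow, integer(1)))), ],
    dplyr::bind_rows(out)
  )
}

#' Normalize feature series per lesion
#'
#' Two conventions: `"preablation"` divides each lesion's series by a
#' pre-ablation reference (by default the last pre-ablation segment value;
#' `pre_reference = "first"` uses the earlier of the two baseline points) —
#' used for the bipolar HF content. `"post30s"` divides by the value of the
#' first valid post-ablation segment (the 30 s point) — used for the
#' unipolar LF content, whose earliest valid reading is 30 s post-ablation.
#' The normalized value at the reference time is exactly 1.
#'
#' @param features Feature tibble from [build_feature_series()] (any number
#'   of lesions/bands; normalization is per `lesion_id` x `channel_band`).
#' @param mode `"preablation"`, `"post30s"` or `"none"`.
#' @param pre_reference `"last"` (default) or `"first"` pre-ablation point.
#' @return `features` with columns `normalized` and `normalization_mode`;
#'   series whose reference is missing or non-positive get `NA` normalized
#'   values.
#' @export
normalize_series <- function(features,
                             mode = c("preablation", "post30s", "none"),
                             pre_reference = c("last", "first")) {
  mode <- match.arg(mode)
  pre_reference <- match.arg(pre_reference)
  if (mode == "none") {
    features$normalized <- features$value_mV
    features$normalization_mode <- "none"
    return(features)
  }
  ref_fun <- function(t_rel_s, value_mV, valid) {
    ok <- valid & !is.na(value_mV)
    if (mode == "preablation") {
      cand <- which(ok & t_rel_s < 0)
      if (length(cand) == 0) return(NA_real_)
      i <- if (pre_reference == "last") cand[length(cand)] else cand[1]
    } else {
      cand <- which(ok & t_rel_s > 0)
      if (length(cand) == 0) return(NA_real_)
      i <- cand[1]
    }
    value_mV[i]
  }
  features |>
    dplyr::group_by(.data$lesion_id, .data$channel_band) |>
    dplyr::mutate(
      .ref = ref_fun(.data$t_rel_s, .data$value_mV, .data$valid),
      normalized = dplyr::if_else(
        !is.na(.ref) & .ref > 0 & .data$valid,
        .data$value_mV / .ref, NA_real_),
      normalization_mode = mode
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".ref")
}
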