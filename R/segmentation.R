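# Per-beat atrial windows, non-overlapping 10-second segments aligned to the
# ablation instant, and artifact/validity exclusion rules.
#
# Conventions: sample indices are 1-based (R); window and segment intervals
# are half-open [start, end); all user-facing times are seconds relative to
# the ablation instant.

#' Per-beat atrial analysis windows
#'
#' For each R peak, the window of predominantly atrial activity: 150 ms
#' starting 200 ms before the peak, i.e. samples `[r - 200 ms, r - 50 ms)`.
#' Windows that would start before the record (or end past it) are marked
#' out of bounds and excluded from feature extraction.
#'
#' @param r_peaks Sorted integer R-peak sample indices.
#' @param fs Sampling frequency in Hz.
#' @param record_length Total number of samples.
#' @return Tibble: `beat`, `r_peak_index`, `start`, `end` (half-open),
#'   `in_bounds`, `contaminated` (initialised `FALSE`).
#' @export
extract_atrial_windows <- function(r_peaks, fs, record_length) {
  stopifnot(!is.unsorted(r_peaks, strictly = TRUE))
  start <- r_peaks - round(0.200 * fs)
  len <- round(0.150 * fs)
  tibble::tibble(
    beat = seq_along(r_peaks),
    r_peak_index = as.integer(r_peaks),
    start = as.integer(start),
    end = as.integer(start + len),
    in_bounds = start >= 1L & (start + len - 1L) <= record_length,
    contaminated = FALSE
  )
}

#' Flag artifact-contaminated beats
#'
#' A beat is contaminated on a channel if, inside its atrial window, any
#' sample touches the amplifier rail, its peak-to-peak amplitude exceeds
#' `outlier_factor` times the running median of per-beat peak-to-peak values
#' (movement/contact transients), or the window overlaps a declared
#' saturation interval.
#'
#' @param record A `lesion_record`.
#' @param windows Window tibble from [extract_atrial_windows()].
#' @param channel Channel to inspect: `"bipolar"` or `"unipolar"`.
#' @param outlier_factor Peak-to-peak outlier multiple (default 8).
#' @param running_k Half-width (in beats) of the running median (default 10).
#' @return `windows` with the `contaminated` flag updated (a beat already
#'   flagged stays flagged).
#' @export
flag_contaminated_beats <- function(record, windows,
                                    channel = c("bipolar", "unipolar"),
                                    outlier_factor = 8, running_k = 10) {
  stopifnot(inherits(record, "lesion_record"))
  channel <- match.arg(channel)
  x <- record$signals[[channel]]
  rail <- record$meta$rail_mV
  # amplifier saturation affects the unipolar channel only; bipolar
  # analysis continues from the ablation instant
  sat <- if (channel == "unipolar") record$truth$saturation_interval

  nb <- nrow(windows)
  if (nb == 0) return(windows)
  pp <- rep(NA_real_, nb)
  amax <- rep(NA_real_, nb)
  railed <- rep(FALSE, nb)
  in_sat <- rep(FALSE, nb)
  for (b in seq_len(nb)) {
    if (!windows$in_bounds[b]) next
    seg <- x[windows$start[b]:(windows$end[b] - 1L)]
    pp[b] <- max(seg) - min(seg)
    amax[b] <- max(abs(seg))
    railed[b] <- amax[b] >= rail
    if (!is.null(sat)) {
      in_sat[b] <- windows$start[b] < sat[2] && windows$end[b] > sat[1]
    }
  }
  run_med <- vapply(seq_len(nb), function(b) {
    lo <- max(1L, b - running_k); hi <- min(nb, b + running_k)
    stats::median(pp[lo:hi], na.rm = TRUE)
  }, numeric(1))
  outlier <- !is.na(amax) & !is.na(run_med) & run_med > 0 &
    amax > outlier_factor * run_med
  windows$contaminated <- windows$contaminated | railed | in_sat | outlier
  windows
}

#' Tile a recording into 10-second segments aligned to the ablation
#'
#' Non-overlapping segments whose grid is anchored so one boundary
#' coincides with the ablation instant; beats are assigned to the segment
#' containing their R peak (a beat exactly on a boundary belongs to the
#' later segment). Only complete segments are kept.
#'
#' @param record A `lesion_record`.
#' @param windows Window tibble (after [flag_contaminated_beats()]).
#' @param segment_s Segment duration in seconds (default 10).
#' @return Tibble: `segment`, `start`, `end` (half-open sample interval),
#'   `t_center_rel_s`, `n_beats`, `n_contaminated`, `contaminated_fraction`,
#'   and a list-column `beats` of beat ids in the segment.
#' @export
segment_record <- function(record, windows, segment_s = 10) {
  stopifnot(inherits(record, "lesion_record"))
  fs <- record$fs
  n <- nrow(record$signals)
  abl <- record$ablation_index
  seg_len <- round(segment_s * fs)

  n_pre <- (abl - 1L) %/% seg_len
  n_post <- (n - abl + 1L) %/% seg_len
  starts <- abl + seg_len * seq(-n_pre, n_post - 1L)
  k <- length(starts)

  usable <- windows$in_bounds
  seg_of_beat <- floor((windows$r_peak_index - abl) / seg_len)  # 0 = first post
  rows <- lapply(seq_len(k), function(i) {
    s0 <- starts[i]
    idx <- which(usable & seg_of_beat == (i - 1L - n_pre))
    nc <- sum(windows$contaminated[idx])
    tibble::tibble(
      segment = i,
      start = s0,
      end = s0 + seg_len,
      t_start_rel_s = (s0 - abl) / fs,
      t_center_rel_s = (s0 - abl + seg_len / 2) / fs,
      n_beats = length(idx),
      n_contaminated = nc,
      contaminated_fraction = if (length(idx) > 0) nc / length(idx) else NA_real_,
      beats = list(windows$beat[idx])
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply segment validity rules
#'
#' A segment is invalid on both channels when more than 20% of its beats are
#' contaminated (exactly 20% is retained) or when it contains no beats.
#' Unipolar validity additionally excludes post-ablation segments beginning
#' before ablation + 30 s: after pulsed-field delivery the unipolar
#' amplifier saturates and readings only become valid 30 s post-ablation,
#' and the same start is applied to all modalities so time grids are
#' comparable.
#'
#' @param segments Segment tibble from [segment_record()].
#' @param contamination_limit Exclusion threshold (default 0.20, strict
#'   inequality).
#' @param unipolar_valid_from_s First valid post-ablation time for the
#'   unipolar channel (default 30 s).
#' @return `segments` with logical columns `valid_bipolar`,
#'   `valid_unipolar`.
#' @export
apply_exclusion_rules <- function(segments, contamination_limit = 0.20,
                                  unipolar_valid_from_s = 30) {
  # strict ">" exclusion: a segment with exactly 20% contaminated is retained
  base_ok <- segments$n_beats > 0 &
    !is.na(segments$contaminated_fraction) &
    !(segments$contaminated_fraction > contamination_limit)
  segments$valid_bipolar <- base_ok
  segments$valid_unipolar <- base_ok &
    !(segments$t_start_rel_s >= 0 &
        segments$t_start_rel_s < unipolar_valid_from_s)
  segments
}
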