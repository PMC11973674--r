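# QRS detection on the surface ECG channel: zero-phase high-pass
# prefiltering followed by an adaptive slope-threshold detector in the
# So-Chan family. R-peak times gate the per-beat atrial analysis windows.

#' QRS detector parameters
#'
#' @param hp_cutoff_hz High-pass prefilter cutoff (default 10 Hz).
#' @param zeroed_leading_samples Leading samples forced to zero after
#'   filtering (default 50), so a recording that opens mid-QRS cannot leave
#'   the detector waiting on a half-seen complex.
#' @param slope_filter_parameter,threshold_divisor The adaptive threshold is
#'   `slope_filter_parameter / threshold_divisor` times a running mean of
#'   recent per-beat maximum slopes (defaults 4 and 16: one quarter).
#' @param refractory_ms Minimum distance between detections (default 200 ms).
#' @param init_window_s Seconds used to initialize the running maximum slope
#'   (default 2).
#' @return List of class `"qrs_params"`.
#' @export
qrs_params <- function(hp_cutoff_hz = 10, zeroed_leading_samples = 50,
                       slope_filter_parameter = 4, threshold_divisor = 16,
                       refractory_ms = 200, init_window_s = 2) {
  stopifnot(hp_cutoff_hz > 0, zeroed_leading_samples >= 0,
            slope_filter_parameter > 0, threshold_divisor > 0,
            refractory_ms > 0, init_window_s > 0)
  structure(list(hp_cutoff_hz = hp_cutoff_hz,
                 zeroed_leading_samples = zeroed_leading_samples,
                 slope_filter_parameter = slope_filter_parameter,
                 threshold_divisor = threshold_divisor,
                 refractory_ms = refractory_ms,
                 init_window_s = init_window_s),
            class = "qrs_params")
}

#' Prefilter an ECG trace for QRS detection
#'
#' Zero-phase 4th-order Butterworth high-pass at `p$hp_cutoff_hz`, then the
#' first `p$zeroed_leading_samples` samples are set exactly to zero.
#'
#' @param x Numeric ECG samples (mV).
#' @param fs Sampling frequency in Hz.
#' @param p [qrs_params()].
#' @return Filtered samples, same length as `x`.
#' @export
prefilter_ecg <- function(x, fs, p = qrs_params()) {
  stopifnot(is.numeric(x), length(x) > p$zeroed_leading_samples)
  if (fs <= 2 * p$hp_cutoff_hz) {
    stop("sampling frequency ", fs, " Hz too low for a ", p$hp_cutoff_hz,
         " Hz high-pass", call. = FALSE)
  }
  bf <- signal::butter(2, p$hp_cutoff_hz / (fs / 2), type = "high")
  y <- signal::filtfilt(bf, x)   # filtfilt doubles the order: 4th overall
  if (p$zeroed_leading_samples > 0) {
    y[seq_len(p$zeroed_leading_samples)] <- 0
  }
  y
}

# 5-point weighted slope: s(n) = -2x(n-2) - x(n-1) + x(n+1) + 2x(n+2)
.slope5 <- function(x) {
  n <- length(x)
  s <- numeric(n)
  s[3:(n - 2)] <- -2 * x[1:(n - 4)] - x[2:(n - 3)] +
    x[4:(n - 1)] + 2 * x[5:n]
  s
}

#' Detect R peaks with an adaptive slope threshold
#'
#' Computes a 5-point weighted slope of the prefiltered ECG and scans for
#' threshold crossings of its absolute value. The threshold is
#' `(slope_filter_parameter / threshold_divisor)` times an exponentially
#' updated running mean of recent per-beat maximum absolute slopes,
#' initialized from the first `init_window_s` seconds. Each crossing yields
#' the sample of maximum absolute filtered amplitude within the following
#' 100 ms (ties broken to the earliest sample); detections closer than the
#' refractory period are suppressed.
#'
#' @param x_filtered Prefiltered ECG from [prefilter_ecg()].
#' @param fs Sampling frequency in Hz.
#' @param p [qrs_params()].
#' @return Integer vector of strictly increasing R-peak sample indices.
#' @export
detect_qrs <- function(x_filtered, fs, p = qrs_params()) {
  n <- length(x_filtered)
  init_n <- round(p$init_window_s * fs)
  if (n < init_n) {
    stop("record shorter than the detector initialization window",
         call. = FALSE)
  }
  s <- abs(.slope5(x_filtered))
  refr <- max(1L, round(p$refractory_ms / 1000 * fs))
  search_w <- round(0.100 * fs)

  maxi <- max(s[seq_len(init_n)])
  if (maxi <= 0) return(integer(0))
  peaks <- integer(0)
  pos <- 1L
  chunk <- max(2L * refr, 2048L)
  while (pos <= n) {
    thr <- (p$slope_filter_parameter / p$threshold_divisor) * maxi
    hi <- min(n, pos + chunk - 1L)
    rel <- which(s[pos:hi] > thr)
    if (length(rel) == 0) {
      pos <- hi + 1L
      next
    }
    cross <- pos + rel[1L] - 1L
    w_hi <- min(n, cross + search_w)
    seg <- abs(x_filtered[cross:w_hi])
    peak <- cross + which.max(seg) - 1L   # which.max: earliest on ties
    peaks <- c(peaks, peak)
    beat_max <- max(s[cross:w_hi])
    maxi <- (7 * maxi + beat_max) / 8
    pos <- peak + refr
  }
  peaks
}

#' Detect R peaks on a lesion recording
#'
#' Convenience wrapper: prefilters the ECG channel of a `lesion_record` and
#' runs [detect_qrs()].
#'
#' @param record A `lesion_record`.
#' @param p [qrs_params()].
#' @return Integer vector of R-peak sample indices.
#' @export
detect_r_peaks <- function(record, p = qrs_params()) {
  stopifnot(inherits(record, "lesion_record"))
  detect_qrs(prefilter_ecg(record$signals$ecg, record$fs, p), record$fs, p)
}
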