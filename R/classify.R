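# Early transmurality call from unipolar low-frequency current-of-injury
# recovery after pulsed field ablation. Group-level separation at 60 s
# motivates a per-lesion decision rule; this extrapolates beyond a group
# statistic to an operational classifier, validated on synthetic cohorts
# only (no claim of clinical validity).

#' Score lesions for transmurality prediction
#'
#' The default score is the normalized unipolar LF value at the decision
#' time (nearest valid segment centre within +/-10 s; ties resolved to the
#' later segment). With `mode = "slope"`, the score is the per-lesion
#' recovery slope on `[30 s, decision_time_s]`. Nontransmural lesions
#' recover their current of injury faster, so lower scores indicate
#' nontransmural outcomes in both modes.
#'
#' @param features Normalized `unipolar_LF` feature tibble
#'   (`normalization_mode = "post30s"`), PFA lesions.
#' @param decision_time_s Decision time in seconds post-ablation
#'   (default 60; must be >= 30, the earliest valid unipolar reading).
#' @param mode `"value"` or `"slope"`.
#' @return Tibble: `lesion_id`, `animal_id`, `transmural` (truth if
#'   present), `score`, `score_time_s`.
#' @export
transmurality_scores <- function(features, decision_time_s = 60,
                                 mode = c("value", "slope")) {
  mode <- match.arg(mode)
  stopifnot(decision_time_s >= 30)
  if (any(features$modality == "SHAM")) {
    stop("SHAM recordings have no ablation event to score", call. = FALSE)
  }
  if (any(features$modality == "RFA")) {
    stop("transmurality scoring applies to PFA lesions only: unipolar ",
         "current-of-injury recovery does not discriminate transmurality ",
         "after RFA", call. = FALSE)
  }
  features |>
    dplyr::filter(.data$channel_band == "unipolar_LF") |>
    dplyr::group_by(.data$lesion_id, .data$animal_id, .data$transmural) |>
    dplyr::group_modify(function(df, key) {
      ok <- df[!is.na(df$normalized) & df$t_rel_s > 0, , drop = FALSE]
      if (mode == "slope") {
        sc <- recovery_slope(ok$t_rel_s, ok$normalized,
                             t_from_s = 30, t_to_s = decision_time_s)
        return(tibble::tibble(score = sc, score_time_s = decision_time_s))
      }
      dist <- abs(ok$t_rel_s - decision_time_s)
      cand <- which(dist <= 10 + 1e-9)
      if (length(cand) == 0) {
        return(tibble::tibble(score = NA_real_,
                              score_time_s = NA_real_))
      }
      best <- cand[order(dist[cand], -ok$t_rel_s[cand])][1]
      tibble::tibble(score = ok$normalized[best],
                     score_time_s = ok$t_rel_s[best])
    }) |>
    dplyr::ungroup()
}

#' Calibrate the decision threshold by Youden's J
#'
#' Scans candidate thresholds (midpoints between adjacent sorted scores)
#' and returns the one maximizing Youden's J = sensitivity + specificity -
#' 1 for the rule "transmural if score >= threshold". If several thresholds
#' tie, the midpoint of the optimal range is returned; if no threshold beats
#' J = 0 (indistinguishable score distributions), the pooled median.
#'
#' @param scores Numeric lesion scores.
#' @param transmural Logical ground-truth labels.
#' @return Scalar threshold.
#' @export
calibrate_threshold <- function(scores, transmural) {
  ok <- !is.na(scores) & !is.na(transmural)
  scores <- scores[ok]; transmural <- transmural[ok]
  stopifnot(length(scores) >= 2, any(transmural), any(!transmural))
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  if (length(cand) == 0) return(stats::median(scores))
  j <- vapply(cand, function(th) {
    sens <- mean(scores[transmural] >= th)
    spec <- mean(scores[!transmural] < th)
    sens + spec - 1
  }, numeric(1))
  if (max(j) <= 0) return(stats::median(scores))
  best <- which(j == max(j))
  mean(range(cand[best]))
}

#' Predict lesion transmurality from COI recovery
#'
#' Applies the decision rule to scored PFA lesions: a score below the
#' threshold (fast COI recovery) is called nontransmural; at or above the
#' threshold (slow recovery, persistent injury current) transmural. A score
#' exactly at the threshold is called transmural — the retain-lesion
#' tie-break, erring towards the durable-lesion call.
#'
#' @param features Normalized `unipolar_LF` feature tibble for PFA lesions.
#' @param threshold Decision threshold (from [calibrate_threshold()]).
#' @param decision_time_s,mode Passed to [transmurality_scores()].
#' @return Tibble: scores plus `threshold`, `label` (`"transmural"` /
#'   `"nontransmural"`), and `correct` when ground truth is present.
#' @export
predict_transmurality <- function(features, threshold, decision_time_s = 60,
                                  mode = c("value", "slope")) {
  mode <- match.arg(mode)
  sc <- transmurality_scores(features, decision_time_s, mode)
  sc$threshold <- threshold
  sc$label <- ifelse(sc$score >= threshold, "transmural", "nontransmural")
  if (!all(is.na(sc$transmural))) {
    sc$correct <- (sc$label == "transmural") == sc$transmural
  }
  sc
}

#' Balanced accuracy of transmurality calls
#'
#' @param calls Tibble from [predict_transmurality()] with ground truth.
#' @return Mean of sensitivity and specificity.
#' @export
balanced_accuracy <- function(calls) {
  ok <- !is.na(calls$score) & !is.na(calls$transmural)
  calls <- calls[ok, , drop = FALSE]
  sens <- mean(calls$label[calls$transmural] == "transmural")
  spec <- mean(calls$label[!calls$transmural] == "nontransmural")
  (sens + spec) / 2
}
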