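#' Score detections against ground truth
#'
#' Greedy one-to-one matching of detections to in-audio ground-truth notes
#' by onset, within `match_tol_s`, per recording. True negatives are
#' counted over non-overlapping `block_s`-second blocks of recorded time
#' that contain no ground-truth note onset: a negative block with no
#' detection onset is a TN, one with a detection is (already) an FP. This
#' gives accuracy a well-defined negative universe.
#'
#' @param detections Tibble with `recording_id`, `onset_s`.
#' @param truth Ground-truth notes tibble with `recording_id`, `onset_s`,
#'   `in_audio` (an `fs_deployment` is also accepted).
#' @param sessions Tibble with `recording_id`, `duration_min` giving the
#'   recorded time over which negative blocks are counted.
#' @param match_tol_s Onset matching tolerance, seconds; must be positive.
#' @param block_s Negative-block length, seconds.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `sensitivity`, `false_positive_rate`, `false_negative_rate`.
#' @export
score_detector <- function(detections, truth, sessions,
                           match_tol_s = 0.75, block_s = 1) {
  if (match_tol_s <= 0) abort("match_tol_s must be positive")
  if (inherits(truth, "fs_deployment")) {
    sessions <- truth$recordings
    truth <- truth$notes
  }
  truth <- truth |> filter(.data$in_audio)
  unknown <- setdiff(detections$recording_id, sessions$recording_id)
  if (length(unknown) > 0) {
    abort(paste0("detections reference unknown recordings: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }

  tp <- 0L
  matched_det <- rep(FALSE, nrow(detections))
  for (rid in unique(truth$recording_id)) {
    t_on <- sort(truth$onset_s[truth$recording_id == rid])
    d_idx <- which(detections$recording_id == rid)
    d_on <- detections$onset_s[d_idx]
    used <- rep(FALSE, length(d_on))
    for (o in t_on) {
      free <- which(!used & abs(d_on - o) <= match_tol_s)
      if (length(free) > 0) {
        pick <- free[which.min(abs(d_on[free] - o))]
        used[pick] <- TRUE
        tp <- tp + 1L
      }
    }
    matched_det[d_idx[used]] <- TRUE
  }
  fp <- nrow(detections) - tp
  fn <- nrow(truth) - tp

  # negative universe: per-recording 1 s blocks with no truth onset
  tn <- 0L
  for (r in seq_len(nrow(sessions))) {
    rid <- sessions$recording_id[r]
    n_blocks <- floor(sessions$duration_min[r] * 60 / block_s)
    t_blk <- unique(floor(truth$onset_s[truth$recording_id == rid] / block_s))
    d_blk <- unique(floor(detections$onset_s[detections$recording_id == rid] /
                            block_s))
    neg <- setdiff(seq_len(n_blocks) - 1, t_blk)
    tn <- tn + length(setdiff(neg, d_blk))
  }

  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / max(1, tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    false_negative_rate = if (tp + fn > 0) fn / (tp + fn) else NA_real_
  )
}
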