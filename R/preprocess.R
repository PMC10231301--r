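#' Exclude participants who failed attention checks
#'
#' Removes every trial of flagged participants, per the pre-registered rule.
#'
#' @param trials trial table with a `participant_id` column.
#' @param attention_flags named logical vector (names = participant ids), or
#'   `NULL` to use the table's `attention_failed` column. Every participant in
#'   `trials` must have a flag.
#' @return list with `trials` (retained trials) and `report` (partial
#'   exclusion counts: participants in/excluded, trials in/out).
#' @examples
#' tr <- data.frame(participant_id = rep(c("p1", "p2"), each = 3),
#'                  attention_failed = rep(c(FALSE, TRUE), each = 3))
#' exclude_participants(tr)$report$n_participants_excluded
#' @export
exclude_participants <- function(trials, attention_flags = NULL) {
  assert_columns(trials, "participant_id")
  pids <- unique(as.character(trials$participant_id))
  if (is.null(attention_flags)) {
    assert_columns(trials, "attention_failed")
    attention_flags <- vapply(split(trials$attention_failed, as.character(trials$participant_id)),
                              function(x) any(x), logical(1))
  }
  missing <- setdiff(pids, names(attention_flags))
  if (length(missing) > 0) {
    stop("missing attention flag for participant(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  flagged <- names(attention_flags)[attention_flags[names(attention_flags)] %in% TRUE]
  keep <- !(as.character(trials$participant_id) %in% flagged)
  report <- list(
    n_participants_in = length(pids),
    n_participants_excluded = sum(pids %in% flagged),
    n_trials_in = nrow(trials),
    n_trials_out = sum(keep)
  )
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Exclude implausibly fast and extremely slow trials
#'
#' Applies the two pre-registered response-time rules: trials faster than
#' `min_ms` (fast guesses) are removed first; then the empirical
#' `upper_quantile` threshold is computed over all remaining trials and trials
#' strictly above it are removed. The threshold is recomputed from the data at
#' hand, so a second application of the quantile rule can remove further
#' trials — only the fast-cut is idempotent.
#'
#' @param trials trial table with positive `rt_ms`.
#' @param min_ms lower cutoff in ms (default 100).
#' @param upper_quantile upper trim quantile (default 0.995, i.e. top 0.5%);
#'   inverse empirical-CDF quantile (an observed value), so removal is strict,
#'   ties at the threshold are retained, and at most a `1 - upper_quantile`
#'   fraction of trials is ever trimmed.
#' @return list with `trials` and `report` (class `exclusion_report`):
#'   `n_trials_in`, `n_trials_fast`, `rt_upper_threshold_ms`, `n_trials_slow`,
#'   `n_trials_out`.
#' @export
exclude_rts <- function(trials, min_ms = 100, upper_quantile = 0.995) {
  assert_columns(trials, "rt_ms")
  if (nrow(trials) == 0) stop("cannot apply RT exclusions to an empty trial table", call. = FALSE)
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0)) {
    stop("all rt_ms must be positive and finite", call. = FALSE)
  }
  n_in <- nrow(trials)
  fast <- trials$rt_ms < min_ms
  kept <- trials[!fast, , drop = FALSE]
  thr <- as.numeric(quantile(kept$rt_ms, upper_quantile, type = 1, names = FALSE))
  slow <- kept$rt_ms > thr
  out <- kept[!slow, , drop = FALSE]
  report <- structure(list(
    n_trials_in = n_in,
    n_trials_fast = sum(fast),
    rt_upper_threshold_ms = thr,
    n_trials_slow = sum(slow),
    n_trials_out = nrow(out)
  ), class = "exclusion_report")
  list(trials = out, report = report)
}

#' Apply the full pre-registered exclusion cascade
#'
#' Attention-check participant exclusion, then the fast-trial rule, then the
#' top-quantile trim computed over all trials of retained participants.
#'
#' @inheritParams exclude_participants
#' @inheritParams exclude_rts
#' @return list with `trials` and a combined `exclusion_report`.
#' @export
preprocess_trials <- function(trials, attention_flags = NULL, min_ms = 100,
                              upper_quantile = 0.995) {
  part <- exclude_participants(trials, attention_flags)
  rts <- exclude_rts(part$trials, min_ms, upper_quantile)
  report <- structure(c(
    part$report[c("n_participants_in", "n_participants_excluded")],
    unclass(rts$report)
  ), class = "exclusion_report")
  list(trials = rts$trials, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  if (!is.null(x$n_participants_in)) {
    cat(sprintf("  participants: %d in, %d excluded (attention), %d retained\n",
                x$n_participants_in, x$n_participants_excluded,
                x$n_participants_in - x$n_participants_excluded))
  }
  cat(sprintf("  trials: %d in, %d fast (< rule), %d slow (> %.1f ms), %d retained\n",
              x$n_trials_in, x$n_trials_fast, x$n_trials_slow,
              x$rt_upper_threshold_ms, x$n_trials_out))
  invisible(x)
}

#' Log-transform response times
#'
#' Natural log of RT in ms, correcting the inherent right skew before linear
#' modelling. The flipped value (multiplied by -1, so higher = faster) is a
#' plotting convention only and is never used in model fits.
#'
#' @param rt_ms positive response times in ms.
#' @param flip return the negated log (plotting orientation).
#' @return numeric vector of (optionally flipped) log RTs.
#' @examples
#' transform_rt(1000)          # log(1000) = 6.9078
#' transform_rt(1000, flip = TRUE)
#' @export
transform_rt <- function(rt_ms, flip = FALSE) {
  if (any(!is.finite(rt_ms)) || any(rt_ms <= 0)) {
    stop("rt_ms must be positive and finite to log-transform", call. = FALSE)
  }
  out <- log(rt_ms)
  if (flip) -out else out
}
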