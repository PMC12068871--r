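#' Per-trial firing rates in an event-aligned window
#'
#' Counts spikes in the half-open window `[event + w0, event + w1)` for each
#' trial event and divides by the window width. Trials with a missing event
#' are dropped and counted.
#'
#' @param spike_times sorted spike times, s.
#' @param events per-trial event times, s (NA = missing).
#' @param window numeric length-2 `(w0, w1)` relative to the event, s,
#'   with `w1 > w0`.
#' @return numeric vector of rates (spikes/s), one per non-missing event;
#'   attribute `"n_dropped"` counts missing events.
#' @export
trial_window_rates <- function(spike_times, events, window) {
  if (length(window) != 2L || diff(window) <= 0)
    stop_invalid("window must be (w0, w1) with w1 > w0")
  ok <- !is.na(events)
  ev <- events[ok]
  width <- window[2L] - window[1L]
  counts <- window_counts(spike_times, ev, window)
  structure(counts / width, n_dropped = sum(!ok))
}

# spike counts in [event + w0, event + w1) per event, via binary search
window_counts <- function(spike_times, events, window) {
  lo <- findInterval(events + window[1L], spike_times, left.open = TRUE)
  hi <- findInterval(events + window[2L], spike_times, left.open = TRUE)
  hi - lo
}

# default analysis windows (s, relative to the aligning event)
default_windows <- function() {
  list(
    baseline = c(-0.2, 0),      # pre-stimulus
    post_stim = c(0, 0.4),
    pre_move = c(-0.2, 0),
    post_move = c(0, 0.2),
    post_move_long = c(0, 0.4),
    pre_feedback = c(-0.2, 0),
    post_feedback = c(0, 0.2)
  )
}

# Wilcoxon wrappers that report p = 1 on degenerate (all-tied) input
# instead of erroring; exact null for small n, normal approximation with
# continuity correction otherwise (wilcox.test's own switch).
signed_rank_p <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(1)
  suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
}
rank_sum_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(wilcox.test(a, b)$p.value)
}

#' The six task-modulation window tests for one unit
#'
#' Trials are restricted to correct trials with non-zero-contrast stimuli.
#' The tests compare per-trial firing rates between task-related windows:
#'
#' 1. `stimulus`: pre-stimulus baseline vs post-stimulus (signed-rank);
#' 2. `movement_initiation`: pre- vs post-movement (signed-rank);
#' 3. `left_vs_right_movement`: post-movement rates on left- vs right-choice
#'    trials (rank-sum, unpaired);
#' 4. `feedback`: pre- vs post-feedback (signed-rank);
#' 5. `stimulus_left_vs_right`: post-stimulus rates by stimulus side
#'    (rank-sum);
#' 6. `movement_vs_baseline`: pre-stimulus baseline vs a longer
#'    post-movement window (signed-rank).
#'
#' Each test uses alpha = 0.05 with no unit-level multiple-test correction.
#' A test with fewer than `min_trials` usable trials on either side is
#' reported as undetermined (NA) and excluded from population proportions.
#'
#' @param unit a [unit_record()].
#' @param trials a trial table as from [gen_trial_table()].
#' @param alpha significance level per test (default 0.05).
#' @param windows named list of analysis windows; see `default_windows`
#'   in the package source for the defaults.
#' @param min_trials minimum usable trials per side (default 5).
#' @return an object of class `modulation_result`: data.frame with one row
#'   per test — `test`, `p_value`, `modulated` (p < alpha),
#'   `modulation_magnitude` (mean rate difference, spikes/s; post minus
#'   pre, or left minus right).
#' @export
modulation_tests <- function(unit, trials, alpha = 0.05, windows = NULL,
                             min_trials = 5L) {
  w <- default_windows()
  if (!is.null(windows)) w[names(windows)] <- windows
  tr <- trials[trials$feedback_type == "reward" & trials$contrast > 0, ,
               drop = FALSE]
  st <- unit$spike_times

  rates <- function(events, window) trial_window_rates(st, events, window)

  # silent units (no spikes in either window on any trial) carry no
  # information: undetermined rather than "not modulated"
  paired_test <- function(pre, post) {
    if (length(pre) < min_trials || all(c(pre, post) == 0))
      return(c(p = NA_real_, mag = NA_real_))
    c(p = signed_rank_p(post, pre), mag = mean(post) - mean(pre))
  }
  unpaired_test <- function(a, b) {
    if (length(a) < min_trials || length(b) < min_trials ||
        all(c(a, b) == 0))
      return(c(p = NA_real_, mag = NA_real_))
    c(p = rank_sum_p(a, b), mag = mean(a) - mean(b))
  }

  base <- rates(tr$stim_on, w$baseline)
  res <- rbind(
    stimulus = paired_test(base, rates(tr$stim_on, w$post_stim)),
    movement_initiation = paired_test(rates(tr$first_move, w$pre_move),
                                      rates(tr$first_move, w$post_move)),
    left_vs_right_movement = unpaired_test(
      rates(tr$first_move[tr$choice == "left"], w$post_move),
      rates(tr$first_move[tr$choice == "right"], w$post_move)),
    feedback = paired_test(rates(tr$feedback_time, w$pre_feedback),
                           rates(tr$feedback_time, w$post_feedback)),
    stimulus_left_vs_right = unpaired_test(
      rates(tr$stim_on[tr$side == "left"], w$post_stim),
      rates(tr$stim_on[tr$side == "right"], w$post_stim)),
    movement_vs_baseline = paired_test(base,
                                       rates(tr$first_move, w$post_move_long))
  )
  out <- data.frame(test = rownames(res), p_value = res[, "p"],
                    modulated = res[, "p"] < alpha,
                    modulation_magnitude = res[, "mag"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("modulation_result", "data.frame"))
}

#' Movement-window Fano factor of one unit
#'
#' Variance over mean of per-trial spike counts in a window after movement
#' onset (default 40-200 ms), computed on correct trials with full-contrast
#' right-side stimuli. Uses the unbiased (n-1) variance estimator; the
#' Fano factor is 1 for Poisson counts.
#'
#' @param unit a [unit_record()].
#' @param trials a trial table.
#' @param window numeric `(w0, w1)` after movement onset, s (default
#'   `c(0.040, 0.200)`).
#' @return the Fano factor, or `NA` when fewer than 2 qualifying trials or
#'   when the mean count is zero.
#' @export
fano_factor <- function(unit, trials, window = c(0.040, 0.200)) {
  tr <- trials[trials$feedback_type == "reward" & trials$contrast == 1 &
                 trials$side == "right", , drop = FALSE]
  if (nrow(tr) < 2L) return(NA_real_)
  counts <- window_counts(unit$spike_times, tr$first_move, window)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  var(counts) / m
}

#' Proportion of task-modulated units per session
#'
#' For a given test, the fraction of determined units that are modulated,
#' per session; sessions with fewer than `min_units` QC-passing units in
#' the target region are excluded.
#'
#' @param sessions list of [session_record()] objects.
#' @param test one of the six test names of [modulation_tests()].
#' @param region target region label.
#' @param min_units region unit minimum for session inclusion (default 4).
#' @param alpha per-test significance level (default 0.05).
#' @return data.frame with one row per included session: `lab_id`,
#'   `subject_id`, `session_id`, `n_units`, `n_determined`, `proportion`.
#' @export
proportion_modulated <- function(sessions, test, region, min_units = 4L,
                                 alpha = 0.05) {
  rows <- lapply(sessions, function(s) {
    units <- Filter(function(u) u$region == region, s$units)
    if (length(units) < min_units) return(NULL)
    p <- vapply(units, function(u) {
      mt <- modulation_tests(u, s$trial_table, alpha = alpha)
      mt$p_value[mt$test == test]
    }, numeric(1))
    det <- !is.na(p)
    data.frame(lab_id = s$lab_id, subject_id = s$subject_id,
               session_id = s$session_id, n_units = length(units),
               n_determined = sum(det),
               proportion = if (any(det)) mean(p[det] < alpha) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
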