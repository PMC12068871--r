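#' Construct a QC report
#'
#' @param table data.frame with columns `criterion`, `value`, `threshold`,
#'   `pass` and `reason`.
#' @return object of class `qc_report`; overall `pass` is TRUE iff every
#'   criterion passes.
#' @export
qc_report <- function(table) {
  stopifnot(all(c("criterion", "value", "threshold", "pass", "reason") %in%
                  names(table)))
  structure(list(criteria = table, pass = all(table$pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$criteria))) {
    r <- x$criteria[i, ]
    cat(sprintf("  %-22s %10.4g (threshold %g): %s%s\n", r$criterion,
                r$value, r$threshold, if (r$pass) "pass" else "FAIL",
                if (is.na(r$reason) || !nzchar(r$reason)) ""
                else paste0(" [", r$reason, "]")))
  }
  invisible(x)
}

#' Sliding refractory-period contamination confidence
#'
#' Estimates whether a unit is contaminated by refractory-period violations
#' without assuming the refractory period's length. For each candidate
#' length `t_r` on a log-spaced grid, the observed violation count `k(t_r)`
#' is the number of inter-spike intervals shorter than `t_r`. Under exactly
#' `max_contamination` contamination by an independent Poisson process, the
#' expected violation count is
#' `lambda(t_r) = 2 * t_r * max_contamination * N * r`
#' (N spikes, mean rate r = N/duration; the factor 2 counts a contaminating
#' spike violating against either neighbour). The confidence that true
#' contamination is below `max_contamination` is the Poisson survival
#' probability `P[Poisson(lambda) > k]`; the unit passes if that confidence
#' exceeds 0.9 for any candidate refractory-period length.
#'
#' @param spike_times sorted spike times, s (>= 2 spikes to be determinate).
#' @param duration recording duration, s (> 0).
#' @param rp_min,rp_max bounds of the candidate refractory-period grid, s.
#' @param max_contamination acceptable contamination fraction (default 0.1).
#' @param n_rp number of log-spaced grid points (default 50).
#' @return an object of class `rp_result`: `rp_grid`, `confidence_per_rp`,
#'   `max_confidence`, `pass` and (on degenerate input) `reason`.
#' @export
sliding_rp_confidence <- function(spike_times, duration, rp_min = 0.0005,
                                  rp_max = 0.010, max_contamination = 0.1,
                                  n_rp = 50L) {
  if (duration <= 0) stop_invalid("duration must be > 0")
  grid <- exp(seq(log(rp_min), log(rp_max), length.out = n_rp))
  if (length(spike_times) < 2L) {
    return(structure(list(rp_grid = grid,
                          confidence_per_rp = rep(NA_real_, n_rp),
                          max_confidence = NA_real_, pass = FALSE,
                          reason = "insufficient spikes"),
                     class = "rp_result"))
  }
  isis <- diff(spike_times)
  if (any(isis <= 0)) stop_invalid("spike_times must be strictly increasing")
  n <- length(spike_times)
  rate <- n / duration
  sorted <- sort(isis)
  # k(t_r): consecutive ISIs strictly below t_r
  k <- findInterval(grid, sorted, left.open = TRUE)
  lambda <- 2 * grid * max_contamination * n * rate
  conf <- ppois(k, lambda, lower.tail = FALSE)
  structure(list(rp_grid = grid, confidence_per_rp = conf,
                 max_confidence = max(conf), pass = max(conf) > 0.9,
                 reason = NULL),
            class = "rp_result")
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf("Sliding refractory-period metric: %s (max confidence %.4f)\n",
              if (x$pass) "pass" else "FAIL", x$max_confidence))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Amplitude-cutoff estimate of missed spikes
#'
#' Detects truncation of the low-amplitude tail of a unit's spike-amplitude
#' histogram (a signature of spikes missed by the detection threshold). The
#' amplitude range is binned into `n_bins` equal-width bins; the height of
#' the lowest-amplitude bin is compared with the bins in the highest
#' quantile of the distribution (the top 1/4, by bin index, of bins above
#' the peak bin): `sd_distance = (h_low - mean(h_high)) / sd(h_high)`, and
#' `low_bin_fraction = h_low / h_peak`. The unit passes when
#' `sd_distance < 5` and `low_bin_fraction < 0.1`.
#'
#' @param amplitudes spike amplitudes, uV (>= 50 values to be determinate).
#' @param n_bins histogram bin count (default 100).
#' @return an object of class `cutoff_result`: `sd_distance`,
#'   `low_bin_fraction`, `pass`, `reason`.
#' @export
amplitude_cutoff <- function(amplitudes, n_bins = 100L) {
  fail <- function(reason) structure(
    list(sd_distance = NA_real_, low_bin_fraction = NA_real_,
         pass = FALSE, reason = reason), class = "cutoff_result")
  if (length(amplitudes) < 50L) return(fail("insufficient spikes"))
  rng <- range(amplitudes)
  if (diff(rng) <= 0) return(fail("degenerate distribution"))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(amplitudes, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  peak <- which.max(h)
  above <- if (peak < n_bins) h[(peak + 1L):n_bins] else numeric(0)
  n_high <- ceiling(length(above) / 4)
  high <- if (n_high > 0) tail(above, n_high) else numeric(0)
  h_low <- h[1L]
  if (length(high) < 2L || sd(high) == 0) {
    mh <- if (length(high)) mean(high) else NA_real_
    sd_distance <- if (isTRUE(h_low == mh)) 0 else Inf
  } else {
    sd_distance <- (h_low - mean(high)) / sd(high)
  }
  low_bin_fraction <- h_low / h[peak]
  structure(list(sd_distance = sd_distance,
                 low_bin_fraction = low_bin_fraction,
                 pass = sd_distance < 5 && low_bin_fraction < 0.1,
                 reason = NULL),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Amplitude cutoff: %s (sd distance %.3g, low-bin fraction %.3g)\n",
              if (x$pass) "pass" else "FAIL", x$sd_distance,
              x$low_bin_fraction))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Median spike-amplitude criterion
#'
#' @param amplitudes spike amplitudes, uV.
#' @param threshold pass requires median strictly greater than this
#'   (default 50 uV).
#' @return list with `median`, `pass` and `reason`.
#' @export
median_amplitude_pass <- function(amplitudes, threshold = 50) {
  if (!length(amplitudes))
    return(list(median = NA_real_, pass = FALSE, reason = "no amplitudes"))
  m <- median(amplitudes)
  list(median = m, pass = m > threshold, reason = NULL)
}

#' Run all single-unit QC metrics on one unit
#'
#' Applies the sliding refractory-period metric, the amplitude-cutoff
#' estimate and the median-amplitude criterion; the unit passes overall iff
#' all three pass. Degenerate inputs are reported as failures with reasons,
#' never as errors.
#'
#' @param unit a [unit_record()].
#' @param duration recording duration, s.
#' @param rp_threshold,cutoff_sd,cutoff_frac,amp_threshold criterion
#'   thresholds (defaults: confidence > 0.9, sd distance < 5, low-bin
#'   fraction < 0.1, median amplitude > 50 uV).
#' @return a [qc_report()].
#' @export
unit_qc <- function(unit, duration, rp_threshold = 0.9, cutoff_sd = 5,
                    cutoff_frac = 0.1, amp_threshold = 50) {
  rp <- sliding_rp_confidence(unit$spike_times, duration)
  co <- amplitude_cutoff(unit$amplitudes)
  ma <- median_amplitude_pass(unit$amplitudes, amp_threshold)
  qc_report(data.frame(
    criterion = c("rp_confidence", "cutoff_sd_distance", "cutoff_low_bin",
                  "median_amplitude"),
    value = c(rp$max_confidence, co$sd_distance, co$low_bin_fraction,
              ma$median),
    threshold = c(rp_threshold, cutoff_sd, cutoff_frac, amp_threshold),
    pass = c(isTRUE(rp$max_confidence > rp_threshold),
             isTRUE(co$sd_distance < cutoff_sd),
             isTRUE(co$low_bin_fraction < cutoff_frac),
             ma$pass),
    reason = c(rp$reason %||% NA_character_, co$reason %||% NA_character_,
               co$reason %||% NA_character_, ma$reason %||% NA_character_),
    stringsAsFactors = FALSE
  ))
}
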