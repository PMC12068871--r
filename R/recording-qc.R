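#' Neuron yield per electrode channel
#'
#' @param n_passing_units units passing single-unit QC in the region.
#' @param n_channels electrode channels assigned to the region (> 0).
#' @param threshold pass requires yield >= this (default 0.1
#'   units/channel).
#' @return list with `yield` and `pass`.
#' @export
yield_metric <- function(n_passing_units, n_channels, threshold = 0.1) {
  if (n_channels <= 0) stop_invalid("n_channels must be > 0")
  y <- n_passing_units / n_channels
  list(yield = y, pass = y >= threshold)
}

#' AP-band noise criterion
#'
#' @param ap_rms_per_channel AP-band RMS per channel, uV (non-empty).
#' @param threshold pass requires median strictly below this (default
#'   40 uV).
#' @return list with `median_rms` and `pass`.
#' @export
ap_rms_pass <- function(ap_rms_per_channel, threshold = 40) {
  if (!length(ap_rms_per_channel))
    stop_invalid("ap_rms_per_channel must be non-empty")
  m <- median(ap_rms_per_channel)
  list(median_rms = m, pass = m < threshold)
}

# Welch PSD: averaged modified periodograms with a Hann window and 50%
# overlap. One-sided density normalized so that sum(psd) * df equals the
# signal variance for zero-mean input (up to estimator noise).
welch_psd <- function(x, fs, nperseg = 1024L) {
  n <- length(x)
  if (n < nperseg) stop_invalid("need at least nperseg samples")
  win <- signal::hanning(nperseg)
  step <- nperseg %/% 2L
  starts <- seq(1L, n - nperseg + 1L, by = step)
  scale <- fs * sum(win^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg)[seq_len(nfreq)])^2 / scale
    # one-sided: double everything except DC and Nyquist
    sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]
    acc <- acc + sp
  }
  list(freqs = (seq_len(nfreq) - 1L) * fs / nperseg,
       psd = acc / length(starts))
}

# mean band power in dB over [lo, hi] Hz for each row of a psd_db matrix
band_power_db <- function(psd_db, freqs, lo = 20, hi = 80) {
  sel <- freqs >= lo & freqs <= hi
  if (!any(sel)) stop_invalid("psd does not cover [%g, %g] Hz", lo, hi)
  rowMeans(psd_db[, sel, drop = FALSE])
}

#' LFP power spectral density profile along the probe
#'
#' Per-channel Welch PSD (Hann window of `nperseg` samples, 50% overlap),
#' converted to decibels as `dB = 10 * log10(PSD)`, with the mean dB over
#' the 20-80 Hz band per channel. All-zero channels yield a `-Inf` band
#' power and are flagged.
#'
#' @param lfp numeric matrix, channels x samples, V.
#' @param fs sampling rate, Hz (> 160 so the 80 Hz band edge is resolvable).
#' @param channel_depths channel depths, um (defaults to the row index).
#' @param nperseg Welch segment length, samples (default 1024).
#' @return an object of class `lfp_profile`: `channel_depths`, `freqs`,
#'   `psd_db`, `band`, `band_power_per_channel`, `flagged_channels`.
#' @export
lfp_psd <- function(lfp, fs, channel_depths = NULL, nperseg = 1024L) {
  lfp <- as.matrix(lfp)
  if (ncol(lfp) < nperseg)
    stop_invalid("need at least nperseg = %d samples", nperseg)
  if (fs <= 2 * 80) stop_invalid("fs must exceed 160 Hz")
  if (is.null(channel_depths)) channel_depths <- seq_len(nrow(lfp))
  psd <- t(apply(lfp, 1L, function(ch) welch_psd(ch, fs, nperseg)$psd))
  freqs <- welch_psd(lfp[1L, ], fs, nperseg)$freqs
  psd_db <- 10 * log10(psd)  # all-zero channels go to -Inf
  bp <- band_power_db(psd_db, freqs)
  structure(list(channel_depths = channel_depths, freqs = freqs,
                 psd_db = psd_db, band = c(20, 80),
                 band_power_per_channel = bp,
                 flagged_channels = which(!is.finite(bp))),
            class = "lfp_profile")
}

#' @export
print.lfp_profile <- function(x, ...) {
  cat(sprintf("LFP profile: %d channels, band power (20-80 Hz) %.1f dB median\n",
              length(x$band_power_per_channel),
              median(x$band_power_per_channel[is.finite(x$band_power_per_channel)])))
  if (length(x$flagged_channels))
    cat("  flagged (silent) channels:",
        paste(x$flagged_channels, collapse = ", "), "\n")
  invisible(x)
}

#' LFP band-power depth-derivative criterion
#'
#' The derivative of 20-80 Hz band power along channel depth, by central
#' finite differences in the interior and one-sided differences at the
#' ends; the absolute value is used because the sign depends on probe
#' orientation. Pass requires the median absolute derivative to be strictly
#' below `threshold`.
#'
#' @param profile an `lfp_profile`, or any list with
#'   `band_power_per_channel` and `channel_depths`.
#' @param threshold dB/um (default 0.05).
#' @return list with `median_abs_derivative` and `pass`.
#' @export
lfp_derivative_pass <- function(profile, threshold = 0.05) {
  bp <- profile$band_power_per_channel
  d <- profile$channel_depths
  if (length(bp) < 2L || length(unique(d)) < 2L)
    stop_invalid("need >= 2 channels at distinct depths")
  n <- length(bp)
  deriv <- numeric(n)
  deriv[1L] <- (bp[2L] - bp[1L]) / (d[2L] - d[1L])
  deriv[n] <- (bp[n] - bp[n - 1L]) / (d[n] - d[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    deriv[i] <- (bp[i + 1L] - bp[i - 1L]) / (d[i + 1L] - d[i - 1L])
  }
  m <- median(abs(deriv))
  list(median_abs_derivative = m, pass = m < threshold)
}

#' Whole-recording QC for a session
#'
#' Computes yield per region (passing units per channel), the AP-band noise
#' criterion and the LFP depth-derivative criterion from a session's stored
#' summaries.
#'
#' @param session a [session_record()].
#' @param unit_pass optional logical vector, one per unit, marking units
#'   that pass single-unit QC; defaults to all units passing (useful when
#'   QC flags were computed upstream).
#' @return a [qc_report()] with one yield row per region plus noise and
#'   LFP rows.
#' @export
recording_qc <- function(session, unit_pass = NULL) {
  if (is.null(unit_pass)) unit_pass <- rep(TRUE, length(session$units))
  regions <- names(session$n_channels_per_region)
  unit_regions <- vapply(session$units, function(u) u$region, character(1))
  rows <- lapply(regions, function(r) {
    ym <- yield_metric(sum(unit_pass & unit_regions == r),
                       session$n_channels_per_region[[r]])
    data.frame(criterion = paste0("yield_", r), value = ym$yield,
               threshold = 0.1, pass = ym$pass, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  noise <- ap_rms_pass(session$ap_rms_per_channel)
  prof <- list(band_power_per_channel =
                 band_power_db(session$lfp_psd$psd_db, session$lfp_psd$freqs),
               channel_depths = session$channel_depths)
  lfp <- lfp_derivative_pass(prof)
  qc_report(rbind(
    do.call(rbind, rows),
    data.frame(criterion = "ap_rms", value = noise$median_rms,
               threshold = 40, pass = noise$pass, reason = NA_character_),
    data.frame(criterion = "lfp_derivative",
               value = lfp$median_abs_derivative, threshold = 0.05,
               pass = lfp$pass, reason = NA_character_)
  ))
}
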