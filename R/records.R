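#' Construct a single sorted-unit record
#'
#' @param unit_id identifier, coerced to character.
#' @param spike_times spike times in s from session start; strictly
#'   increasing, >= 0.
#' @param amplitudes spike amplitudes, uV, one per spike, > 0.
#' @param position numeric length-3 (x, y, z) in um, atlas frame.
#' @param ptt_duration waveform peak-to-trough duration, ms.
#' @param region region label, one of `"VISa/am"`, `"CA1"`, `"DG"`, `"LP"`,
#'   `"PO"`, `"other"`.
#' @param qc_flags optional named logical vector of QC outcomes.
#' @return an object of class `unit_record`.
#' @export
unit_record <- function(unit_id, spike_times, amplitudes,
                        position = c(0, 0, 0), ptt_duration = 0.45,
                        region = "other", qc_flags = NULL) {
  spike_times <- as.numeric(spike_times)
  amplitudes <- as.numeric(amplitudes)
  if (length(spike_times) != length(amplitudes))
    stop_invalid("spike_times and amplitudes must have equal length")
  if (length(spike_times) && any(spike_times < 0))
    stop_invalid("spike_times must be >= 0")
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop_invalid("spike_times must be strictly increasing")
  if (length(amplitudes) && any(amplitudes <= 0))
    stop_invalid("amplitudes must be > 0")
  if (length(position) != 3L) stop_invalid("position must be length 3")
  regions <- c("VISa/am", "CA1", "DG", "LP", "PO", "other")
  if (!region %in% regions)
    stop_invalid("region must be one of: %s", paste(regions, collapse = ", "))
  structure(list(
    unit_id = as.character(unit_id), spike_times = spike_times,
    amplitudes = amplitudes, position = as.numeric(position),
    ptt_duration = ptt_duration, region = region, qc_flags = qc_flags
  ), class = "unit_record")
}

#' @export
print.unit_record <- function(x, ...) {
  cat(sprintf("Unit %s [%s]: %d spikes, median amplitude %.1f uV\n",
              x$unit_id, x$region, length(x$spike_times),
              if (length(x$amplitudes)) median(x$amplitudes) else NA))
  invisible(x)
}

# fixed cascade order; behavior and lab_count are appended by the cascade
ledger_criteria <- function() {
  c("hardware", "histology", "drift", "noisy_channels", "artefact",
    "epileptiform", "yield", "noise")
}

#' Construct a session (single insertion) record
#'
#' @param lab_id,subject_id,session_id identifiers.
#' @param units list of [unit_record()] objects.
#' @param n_channels_per_region named integer vector, channels per region.
#' @param channel_depths channel depths along the probe, um.
#' @param ap_rms_per_channel AP-band RMS per channel, uV.
#' @param lfp_psd list with `freqs` (Hz) and `psd_db` (channels x
#'   frequencies, dB); frequencies must cover \[20, 80\] Hz.
#' @param trial_table a trial table as from [gen_trial_table()].
#' @param planned_traj,micro_traj,histology_traj [trajectory()] objects or
#'   `NULL`.
#' @param exclusion_ledger named logical vector (TRUE = pass) over the fixed
#'   criterion order `hardware, histology, drift, noisy_channels, artefact,
#'   epileptiform, yield, noise`.
#' @return an object of class `session_record`.
#' @export
session_record <- function(lab_id, subject_id, session_id, units = list(),
                           n_channels_per_region = NULL,
                           channel_depths = NULL, ap_rms_per_channel = NULL,
                           lfp_psd = NULL, trial_table = NULL,
                           planned_traj = NULL, micro_traj = NULL,
                           histology_traj = NULL,
                           exclusion_ledger = NULL) {
  if (is.null(exclusion_ledger)) {
    exclusion_ledger <- setNames(rep(TRUE, length(ledger_criteria())),
                                 ledger_criteria())
  }
  if (!all(names(exclusion_ledger) == ledger_criteria()))
    stop_invalid("exclusion_ledger must carry the fixed criterion order: %s",
                 paste(ledger_criteria(), collapse = ", "))
  if (!is.null(lfp_psd)) {
    if (min(lfp_psd$freqs) > 20 || max(lfp_psd$freqs) < 80)
      stop_invalid("lfp_psd frequencies must cover [20, 80] Hz")
  }
  structure(list(
    lab_id = as.character(lab_id), subject_id = as.character(subject_id),
    session_id = as.character(session_id), units = units,
    n_channels_per_region = n_channels_per_region,
    channel_depths = channel_depths,
    ap_rms_per_channel = ap_rms_per_channel, lfp_psd = lfp_psd,
    trial_table = trial_table, planned_traj = planned_traj,
    micro_traj = micro_traj, histology_traj = histology_traj,
    exclusion_ledger = exclusion_ledger
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session %s (%s / %s): %d units, %d trials\n",
              x$session_id, x$lab_id, x$subject_id, length(x$units),
              if (is.null(x$trial_table)) 0L else nrow(x$trial_table)))
  failed <- names(x$exclusion_ledger)[!x$exclusion_ledger]
  if (length(failed)) cat("  failed criteria:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}
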