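# Region-specific event-locked response templates. Each template is a
# sampler of extra-spike latencies relative to movement onset; the set is a
# minimal basis (transient, step, ramp, late step, none) sufficient to make
# the five regions separable in a PETH embedding.
region_template <- function(region) {
  switch(region,
    "VISa/am" = list(gain = 1.0, sample = function(n) {
      pmin(pmax(rnorm(n, 0.05, 0.05), -0.1), 0.3)
    }),
    "CA1" = list(gain = 0.9, sample = function(n) runif(n, 0, 0.4)),
    "DG" = list(gain = 0, sample = function(n) numeric(0)),
    "LP" = list(gain = 1.1, sample = function(n) 0.5 * sqrt(runif(n))),
    "PO" = list(gain = 0.8, sample = function(n) runif(n, 0.3, 0.8)),
    list(gain = 0, sample = function(n) numeric(0))
  )
}

# depth bands (um along the probe) occupied by each region
region_depth_bands <- function() {
  list("VISa/am" = c(50, 900), "CA1" = c(1100, 1500), "DG" = c(1600, 2000),
       "LP" = c(2200, 2800), "PO" = c(2900, 3500))
}

lab_shift <- function(config, lab_id, feature) {
  eff <- config$lab_effects[[lab_id]]
  if (is.null(eff)) 0 else eff[[feature]] %||% 0
}

#' Generate a hierarchical multi-lab population of synthetic sessions
#'
#' Builds the full lab -> mouse -> session -> unit hierarchy the
#' reproducibility analyses operate on. With `lab_effects` absent the
#' per-mouse feature values are exchangeable across labs (the null
#' hypothesis of the permutation framework); with `lab_effects` set, the
#' named lab's values are shifted additively (the alternative). Each unit
#' carries an event-locked firing-rate modulation drawn from its region's
#' response template, so regions are separable in the PETH embedding while
#' labs (balanced over regions) are not.
#'
#' @param config a [synth_config()] object.
#' @return a list of [session_record()] objects; the generating config is
#'   attached as attribute `"config"`.
#' @export
gen_multilab_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sessions <- list()
  counter <- 0L
  for (l in seq_len(config$n_labs)) {
    lab_id <- sprintf("lab_%02d", l)
    for (m in seq_len(config$mice_per_lab)) {
      subject_id <- sprintf("%s_mouse_%02d", lab_id, m)
      counter <- counter + 1L
      mouse_seed <- child_seed(config$seed, counter)
      # mouse-level random effect, shared across the mouse's sessions
      mouse_factor <- local_seed(mouse_seed, rlnorm(1, 0, 0.2))
      for (s in seq_len(config$sessions_per_mouse)) {
        counter <- counter + 1L
        sessions[[length(sessions) + 1L]] <- gen_session(
          config, lab_id, subject_id,
          session_id = sprintf("%s_ses_%02d", subject_id, s),
          mouse_factor = mouse_factor,
          seed = child_seed(config$seed, counter)
        )
      }
    }
  }
  attr(sessions, "config") <- config
  sessions
}

# One synthetic insertion: trial table, units with event-locked modulation,
# channel summaries, LFP depth profile and trajectories.
gen_session <- function(config, lab_id, subject_id, session_id, mouse_factor,
                        seed) {
  local_seed(seed, {
    trials <- gen_trial_table(config$n_trials, config$rt_mean)
    duration <- max(trials$feedback_time) + 5

    rate_shift <- lab_shift(config, lab_id, "firing_rate")
    amp_shift <- lab_shift(config, lab_id, "amplitude")
    rms_shift <- lab_shift(config, lab_id, "ap_rms")
    lfp_shift <- lab_shift(config, lab_id, "lfp_power")

    bands <- region_depth_bands()
    units <- list()
    uid <- 0L
    for (region in names(config$units_per_region)) {
      tmpl <- region_template(region)
      band <- bands[[region]] %||% c(0, 3500)
      for (u in seq_len(config$units_per_region[[region]])) {
        uid <- uid + 1L
        rate <- max(0.5, (config$base_rate + rate_shift) *
                      mouse_factor * rlnorm(1, 0, 0.4))
        st <- gen_spike_train(rate, duration, config$refractory,
                              contamination = 0)
        # event-locked extra spikes per trial, template-shaped; the merged
        # train is re-thinned so the unit itself respects the refractory
        # period, then contamination is injected on top
        if (tmpl$gain > 0) {
          per_trial <- rpois(nrow(trials), tmpl$gain * rate * 0.4)
          extra <- rep(trials$first_move, per_trial) +
            tmpl$sample(sum(per_trial))
          st <- thin_refractory(sort(c(st, extra[extra > 0 &
                                                   extra < duration])),
                                config$refractory)
        }
        if (config$contamination > 0) {
          cont <- poisson_times(config$contamination /
                                  (1 - config$contamination) * rate,
                                duration)
          st <- unique(sort(c(st, cont)))
        }
        amp_mu <- config$amp_mean + amp_shift + rnorm(1, 0, config$amp_sd / 2)
        amps <- rnorm(length(st), amp_mu, config$amp_sd)
        if (!is.null(config$amp_truncation)) {
          keep <- amps >= config$amp_truncation
          st <- st[keep]
          amps <- amps[keep]
        }
        amps <- pmax(amps, 1)  # uV, physical floor
        units[[uid]] <- unit_record(
          unit_id = sprintf("%s_u%04d", session_id, uid),
          spike_times = st, amplitudes = amps,
          position = c(2000 + rnorm(1, 0, 150), -2240 + rnorm(1, 0, 150),
                       runif(1, band[1], band[2])),
          ptt_duration = 0.1 + abs(rnorm(1, 0.35, 0.12)),
          region = region
        )
      }
    }

    channel_depths <- seq(0, 3830, by = 10)
    n_per_region <- vapply(names(config$units_per_region), function(r) {
      b <- bands[[r]] %||% c(0, 3500)
      sum(channel_depths >= b[1] & channel_depths <= b[2])
    }, integer(1))
    ap_rms <- abs(rnorm(length(channel_depths), 20 + rms_shift, 3))

    freqs <- seq(1, 100, by = 1)
    dg_bump <- 10 * exp(-((channel_depths - 1800) / 200)^2)
    psd_db <- outer(dg_bump, rep(1, length(freqs))) +
      outer(rep(1, length(channel_depths)), -30 - 0.05 * freqs) +
      lfp_shift + matrix(rnorm(length(channel_depths) * length(freqs), 0, 0.1),
                         nrow = length(channel_depths))

    planned <- planned_repeated_site()
    hist_dir <- planned$direction + rnorm(3, 0, 0.03)
    session_record(
      lab_id = lab_id, subject_id = subject_id, session_id = session_id,
      units = units, n_channels_per_region = n_per_region,
      channel_depths = channel_depths, ap_rms_per_channel = ap_rms,
      lfp_psd = list(freqs = freqs, psd_db = psd_db),
      trial_table = trials,
      planned_traj = planned,
      micro_traj = trajectory(planned$entry + c(rnorm(2, 0, 100), 0),
                              planned$direction, "micromanipulator"),
      histology_traj = trajectory(planned$entry + c(rnorm(2, 0, 200), 0),
                                  hist_dir, "histology")
    )
  })
}

#' Session duration implied by the trial table
#'
#' Defined as the last feedback time plus a 5 s tail; used wherever a
#' recording duration is needed (firing rates, refractory-period metric).
#'
#' @param session a [session_record()].
#' @return duration in s.
#' @export
session_duration <- function(session) {
  if (is.null(session$trial_table) || !nrow(session$trial_table))
    stop_invalid("session has no trial table")
  max(session$trial_table$feedback_time) + 5
}

#' Per-recording electrophysiological feature summary
#'
#' The five markers used in the across-lab feature comparisons and the lab
#' decoding test: neuron yield (units per channel), mean firing rate,
#' LFP band power (20-80 Hz), median AP-band RMS, and median spike
#' amplitude.
#'
#' @param session a [session_record()].
#' @return named numeric vector of length 5.
#' @export
session_features <- function(session) {
  dur <- session_duration(session)
  n_units <- length(session$units)
  rates <- vapply(session$units,
                  function(u) length(u$spike_times) / dur, numeric(1))
  med_amp <- vapply(session$units, function(u) {
    if (length(u$amplitudes)) median(u$amplitudes) else NA_real_
  }, numeric(1))
  band <- band_power_db(session$lfp_psd$psd_db, session$lfp_psd$freqs)
  c(yield = n_units / length(session$channel_depths),
    firing_rate = mean(rates),
    lfp_power = mean(band),
    ap_rms = median(session$ap_rms_per_channel),
    spike_amplitude = median(med_amp, na.rm = TRUE))
}
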