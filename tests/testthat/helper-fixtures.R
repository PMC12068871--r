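# Shared fixture builders: everything is generated in code at test time.

# A small multi-lab population (5 labs x 2 mice by default) cached per
# argument set so several tests can share one generation pass.
.pop_cache <- new.env(parent = emptyenv())
small_population <- function(seed = 11, n_labs = 5, mice_per_lab = 2,
                             units_per_region = c("VISa/am" = 4, CA1 = 4,
                                                  DG = 4, LP = 4, PO = 4),
                             n_trials = 150, lab_effects = NULL, ...) {
  key <- paste(deparse(list(seed, n_labs, mice_per_lab, units_per_region,
                            n_trials, lab_effects, ...)), collapse = "")
  key <- digest_key(key)
  if (is.null(.pop_cache[[key]])) {
    cfg <- synth_config(seed = seed, n_labs = n_labs,
                        mice_per_lab = mice_per_lab,
                        units_per_region = units_per_region,
                        n_trials = n_trials, lab_effects = lab_effects, ...)
    .pop_cache[[key]] <- gen_multilab_population(cfg)
  }
  .pop_cache[[key]]
}

digest_key <- function(s) {
  # cheap deterministic key without extra deps
  paste0("k", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9)
}

# A unit with a perfectly regular spike train (rate sp/s) and Gaussian
# amplitudes; regular trains make window rates deterministic.
regular_unit <- function(rate = 10, duration = 100, amp_mean = 150,
                         region = "CA1", seed = 1) {
  st <- seq(0, duration, by = 1 / rate)
  st <- st[st > 0 & st < duration]
  unit_record("reg", st, gen_amplitudes(length(st), amp_mean, 10, seed = seed),
              region = region)
}

# Minimal valid session wrapping given units and trials.
quick_session <- function(units, trials, lab_id = "lab_01",
                          subject_id = "m1", session_id = "s1") {
  freqs <- seq(1, 100)
  depths <- seq(0, 3830, by = 10)
  session_record(
    lab_id = lab_id, subject_id = subject_id, session_id = session_id,
    units = units,
    n_channels_per_region = c("VISa/am" = 86, CA1 = 41, DG = 41, LP = 61,
                              PO = 61),
    channel_depths = depths,
    ap_rms_per_channel = rep(20, length(depths)),
    lfp_psd = list(freqs = freqs,
                   psd_db = matrix(-30, length(depths), length(freqs))),
    trial_table = trials
  )
}

# Ledger helper: a session failing exactly the named criterion (or none).
ledger_session <- function(id, fail = NULL, n_trials = 450,
                           lab_id = "lab_01") {
  ledger <- setNames(rep(TRUE, 8), c("hardware", "histology", "drift",
                                     "noisy_channels", "artefact",
                                     "epileptiform", "yield", "noise"))
  if (!is.null(fail) && fail != "behavior") ledger[[fail]] <- FALSE
  if (identical(fail, "behavior")) n_trials <- 100
  trials <- gen_trial_table(n_trials, seed = 1)
  s <- quick_session(list(), trials, lab_id = lab_id, session_id = id)
  s$exclusion_ledger <- ledger
  s
}

# The published exclusion bookkeeping: 121 recorded sessions with the
# printed per-criterion failure counts.
printed_cascade_sessions <- function() {
  fails <- c(rep("hardware", 10), rep("histology", 8), rep("drift", 1),
             rep("noisy_channels", 10), rep("artefact", 2),
             rep("epileptiform", 1), rep("yield", 1), rep("noise", 1),
             rep("behavior", 5))
  sessions <- list()
  for (i in seq_along(fails))
    sessions[[i]] <- ledger_session(sprintf("fail_%03d", i), fails[i])
  for (i in seq_len(121 - length(fails)))
    sessions[[length(fails) + i]] <-
      ledger_session(sprintf("pass_%03d", i),
                     lab_id = sprintf("lab_%02d", (i %% 10) + 1))
  sessions
}
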