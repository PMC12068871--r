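#' Configuration for the synthetic multi-lab population generator
#'
#' Bundles every knob of the synthetic-data module. The defaults describe a
#' realistic standardized multi-lab study: 10 laboratories, 4 mice per lab,
#' one insertion per mouse targeting five brain regions, units firing around
#' 6 spikes/s with a 2 ms absolute refractory period and no contamination,
#' spike amplitudes around 150 uV, and 500-trial sessions with biased
#' stimulus-side blocks and a mean reaction time of 0.15 s.
#'
#' @param seed integer; master seed. Identical configs give bit-identical
#'   populations.
#' @param n_labs,mice_per_lab,sessions_per_mouse hierarchy sizes.
#' @param units_per_region named integer vector over the five target regions
#'   (`"VISa/am"`, `"CA1"`, `"DG"`, `"LP"`, `"PO"`): sorted units per region.
#' @param base_rate baseline firing rate, spikes/s.
#' @param refractory absolute refractory period, s (> 0).
#' @param contamination fraction in \[0, 1\] of contaminating spikes that
#'   ignore the refractory period.
#' @param amp_mean,amp_sd spike amplitude distribution, uV.
#' @param amp_truncation uV or `NULL`; if set, amplitudes below it are
#'   discarded (emulating detection-threshold cutoff).
#' @param lab_effects `NULL` (the across-lab null) or a named list mapping a
#'   lab id (`"lab_01"`, ...) to additive shifts per feature, e.g.
#'   `list(lab_03 = list(firing_rate = 10))`. Supported features:
#'   `firing_rate` (spikes/s), `amplitude` (uV), `ap_rms` (uV),
#'   `lfp_power` (dB).
#' @param n_trials trials per session.
#' @param rt_mean mean reaction time, s.
#'
#' @return an object of class `synth_config`.
#' @seealso [gen_multilab_population()], [read_synth_config()]
#' @export
synth_config <- function(seed = 1L,
                         n_labs = 10L,
                         mice_per_lab = 4L,
                         sessions_per_mouse = 1L,
                         units_per_region = c("VISa/am" = 20L, CA1 = 20L,
                                              DG = 20L, LP = 20L, PO = 20L),
                         base_rate = 6,
                         refractory = 0.002,
                         contamination = 0,
                         amp_mean = 150,
                         amp_sd = 30,
                         amp_truncation = NULL,
                         lab_effects = NULL,
                         n_trials = 500L,
                         rt_mean = 0.15) {
  counts <- c(n_labs, mice_per_lab, sessions_per_mouse, n_trials,
              units_per_region)
  if (any(counts < 0)) stop_invalid("all counts must be >= 0")
  if (refractory <= 0) stop_invalid("refractory must be > 0")
  if (contamination < 0 || contamination > 1)
    stop_invalid("contamination must be in [0, 1]")
  if (base_rate < 0) stop_invalid("base_rate must be >= 0")
  if (amp_sd < 0) stop_invalid("amp_sd must be >= 0")
  if (!is.null(lab_effects) && is.null(names(lab_effects)))
    stop_invalid("lab_effects must be a named list (lab id -> shifts)")
  structure(list(
    seed = as.integer(seed), n_labs = as.integer(n_labs),
    mice_per_lab = as.integer(mice_per_lab),
    sessions_per_mouse = as.integer(sessions_per_mouse),
    units_per_region = units_per_region, base_rate = base_rate,
    refractory = refractory, contamination = contamination,
    amp_mean = amp_mean, amp_sd = amp_sd, amp_truncation = amp_truncation,
    lab_effects = lab_effects, n_trials = as.integer(n_trials),
    rt_mean = rt_mean
  ), class = "synth_config")
}

#' Read a generator configuration from a YAML file
#'
#' Field names and semantics match [synth_config()]; absent fields take the
#' defaults.
#'
#' @param path path to a YAML file.
#' @return a `synth_config` object.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$units_per_region))
    raw$units_per_region <- unlist(raw$units_per_region)
  do.call(synth_config, raw)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic population config\n")
  cat(sprintf("  %d labs x %d mice x %d session(s); seed %d\n",
              x$n_labs, x$mice_per_lab, x$sessions_per_mouse, x$seed))
  cat(sprintf("  units/region: %s\n",
              paste(names(x$units_per_region), x$units_per_region,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  base rate %.3g sp/s, refractory %.3g ms, contamination %.3g\n",
              x$base_rate, 1000 * x$refractory, x$contamination))
  cat(sprintf("  amplitudes %.3g +/- %.3g uV%s\n", x$amp_mean, x$amp_sd,
              if (is.null(x$amp_truncation)) ""
              else sprintf(", truncated at %.3g uV", x$amp_truncation)))
  cat(sprintf("  %d trials/session, mean RT %.3g s\n", x$n_trials, x$rt_mean))
  if (!is.null(x$lab_effects))
    cat("  lab effects:", paste(names(x$lab_effects), collapse = ", "), "\n")
  invisible(x)
}
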