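#' Generate a spike train with refractoriness and controlled contamination
#'
#' The uncontaminated component is a homogeneous Poisson process thinned so
#' that no inter-spike interval is shorter than the absolute refractory
#' period (a spike closer than `refractory` to its accepted predecessor is
#' deleted). Contaminating spikes are injected as an independent homogeneous
#' Poisson process at rate `contamination / (1 - contamination) * rate` and
#' merged in, so that a fraction of approximately `contamination` of all
#' spikes ignores the refractory constraint — the contamination model under
#' which the sliding refractory-period metric is calibrated.
#'
#' @param rate firing rate of the refractory component, spikes/s (>= 0).
#' @param duration recording duration, s (> 0).
#' @param refractory absolute refractory period, s (> 0).
#' @param contamination fraction in \[0, 1).
#' @param seed optional integer seed (local to this call).
#' @return sorted, strictly increasing spike times in \[0, duration\].
#' @examples
#' st <- gen_spike_train(20, 60, refractory = 0.002, seed = 1)
#' min(diff(st)) >= 0.002
#' @export
gen_spike_train <- function(rate, duration, refractory = 0.002,
                            contamination = 0, seed = NULL) {
  if (rate < 0) stop_invalid("rate must be >= 0")
  if (duration <= 0) stop_invalid("duration must be > 0")
  if (refractory <= 0) stop_invalid("refractory must be > 0")
  if (contamination < 0 || contamination >= 1)
    stop_invalid("contamination must be in [0, 1)")
  local_seed(seed, {
    base <- poisson_times(rate, duration)
    base <- thin_refractory(base, refractory)
    cont_rate <- contamination / (1 - contamination) * rate
    cont <- poisson_times(cont_rate, duration)
    st <- sort(c(base, cont))
    # ties have probability zero but would break strict monotonicity
    unique(st)
  })
}

# Homogeneous Poisson event times on [0, duration].
poisson_times <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- rpois(1L, rate * duration)
  sort(runif(n, 0, duration))
}

# Sequential thinning: drop any spike closer than rp to the last kept one.
thin_refractory <- function(times, rp) {
  n <- length(times)
  if (n < 2L) return(times)
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- times[1L]
  for (i in 2:n) {
    if (times[i] - last >= rp) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Generate spike amplitudes with optional detection-threshold truncation
#'
#' Draws `n` Gaussian amplitudes; if `truncation` is set, draws below it are
#' discarded (no redrawing), emulating spikes missed by a deconvolution
#' threshold — the returned vector is the surviving subset, of length <= n.
#'
#' @param n number of draws (>= 0).
#' @param mean,sd Gaussian parameters, uV (sd >= 0).
#' @param truncation uV or `NULL`.
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of amplitudes, uV.
#' @export
gen_amplitudes <- function(n, mean = 150, sd = 30, truncation = NULL,
                           seed = NULL) {
  if (n < 0) stop_invalid("n must be >= 0")
  if (sd < 0) stop_invalid("sd must be >= 0")
  local_seed(seed, {
    a <- rnorm(n, mean, sd)
    if (!is.null(truncation)) a <- a[a >= truncation]
    a
  })
}
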