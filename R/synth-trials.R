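#' Generate a behavioural trial table with biased stimulus-side blocks
#'
#' Emulates the structure of a standardized visual decision-making session:
#' an initial unbiased block (p_left = 0.5) followed by alternating biased
#' blocks in which the stimulus appears on the left with probability 0.2 or
#' 0.8 (20:80 / 80:20), block lengths drawn between 20 and 100 trials.
#' Stimulus contrast is drawn from \{0, 0.0625, 0.125, 0.25, 1\}; reaction
#' times are log-normal with mean `rt_mean`, so a session straddles the
#' 0.15 s fast/slow split; event times obey
#' `stim_on < first_move < feedback_time` on every trial.
#'
#' @param n_trials number of trials (>= 1).
#' @param rt_mean mean reaction time, s.
#' @param seed optional integer seed (local to this call).
#' @return a `data.frame` with one row per trial and columns `trial`,
#'   `stim_on`, `contrast`, `side`, `block_p_left`, `first_move`, `choice`,
#'   `feedback_type`, `feedback_time`, `reaction_time` (s where temporal).
#' @export
gen_trial_table <- function(n_trials, rt_mean = 0.15, seed = NULL) {
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  n_trials <- as.integer(n_trials)
  local_seed(seed, {
    # block identities: unbiased lead-in, then alternating 20:80 / 80:20
    p_left <- numeric(0)
    first_biased <- sample(c(0.2, 0.8), 1L)
    p <- 0.5
    while (length(p_left) < n_trials) {
      len <- if (p == 0.5) 90L else sample(20:100, 1L)
      p_left <- c(p_left, rep(p, len))
      p <- if (p == 0.5) first_biased else if (p == 0.2) 0.8 else 0.2
    }
    p_left <- p_left[seq_len(n_trials)]

    side <- ifelse(runif(n_trials) < p_left, "left", "right")
    contrast <- sample(c(0, 0.0625, 0.125, 0.25, 1), n_trials, replace = TRUE)

    # log-normal RTs with mean rt_mean
    sdlog <- 0.6
    rt <- rlnorm(n_trials, meanlog = log(rt_mean) - sdlog^2 / 2, sdlog = sdlog)

    iti <- 1.5 + rexp(n_trials, rate = 2)
    stim_on <- cumsum(iti + c(0, rt[-n_trials] + 1.0))
    first_move <- stim_on + rt
    feedback_time <- first_move + 0.1 + runif(n_trials, 0, 0.05)

    # accuracy rises with contrast; chance at zero contrast
    p_correct <- 0.5 + 0.45 * sqrt(contrast)
    correct <- runif(n_trials) < p_correct
    choice <- ifelse(correct, side, ifelse(side == "left", "right", "left"))
    feedback_type <- ifelse(choice == side, "reward", "error")

    data.frame(
      trial = seq_len(n_trials), stim_on = stim_on, contrast = contrast,
      side = side, block_p_left = p_left, first_move = first_move,
      choice = choice, feedback_type = feedback_type,
      feedback_time = feedback_time, reaction_time = rt,
      stringsAsFactors = FALSE
    )
  })
}
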