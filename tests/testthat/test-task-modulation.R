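test_that("trial window rates use half-open windows and count correctly", {
  expect_equal(as.numeric(trial_window_rates(numeric(0), c(1, 2), c(0, 0.5))),
               c(0, 0))
  # spike exactly at event+w0 is counted, exactly at event+w1 is not
  r_lo <- trial_window_rates(c(1.0), 1.0, c(0, 0.5))
  r_hi <- trial_window_rates(c(1.5), 1.0, c(0, 0.5))
  expect_equal(as.numeric(r_lo), 2)
  expect_equal(as.numeric(r_hi), 0)
  # uniform 10 sp/s train: window rates average to 10
  st <- seq(0.05, 100, by = 0.1)
  r <- trial_window_rates(st, seq(5, 90, by = 1), c(-0.2, 0.3))
  expect_equal(mean(r), 10, tolerance = 0.05)
  # missing events dropped and counted
  r2 <- trial_window_rates(st, c(1, NA, 3), c(0, 1))
  expect_length(r2, 2)
  expect_equal(attr(r2, "n_dropped"), 1)
  expect_error(trial_window_rates(st, 1, c(0.5, 0.5)), "window")
})

test_that("modulation tests detect injected movement modulation", {
  trials <- gen_trial_table(220, seed = 21)
  dur <- max(trials$feedback_time) + 5
  base <- gen_spike_train(5, dur, seed = 22)
  # double the rate for 200 ms after movement onset
  extra <- unlist(lapply(trials$first_move,
                         function(m) m + runif(2, 0, 0.2)))
  unit <- unit_record("mod", sort(unique(c(base, extra))),
                      rep(100, length(unique(c(base, extra)))))
  res <- modulation_tests(unit, trials)
  expect_s3_class(res, "modulation_result")
  expect_true(res$modulated[res$test == "movement_initiation"])
  expect_gt(res$modulation_magnitude[res$test == "movement_initiation"], 0)
})

test_that("degenerate units give p = 1 (identical) or undetermined (silent)", {
  trials <- gen_trial_table(100, seed = 23)
  # identical nonzero rates pre/post: one spike per 100 ms everywhere
  dur <- max(trials$feedback_time) + 5
  ident <- regular_unit(rate = 10, duration = dur)
  res <- modulation_tests(ident, trials)
  paired <- res$test %in% c("stimulus", "movement_initiation", "feedback",
                            "movement_vs_baseline")
  expect_true(all(res$p_value[paired] > 0.99))
  expect_true(all(!res$modulated[paired]))

  silent <- unit_record("quiet", numeric(0), numeric(0))
  res_s <- modulation_tests(silent, trials)
  expect_true(all(is.na(res_s$p_value)))
})

test_that("modulation tests hold their false-positive rate under the null", {
  # stationary Poisson units: each test should reject ~5% of the time
  n_units <- 150
  trials <- gen_trial_table(120, seed = 30)
  dur <- max(trials$feedback_time) + 5
  pvals <- t(vapply(seq_len(n_units), function(i) {
    st <- gen_spike_train(8, dur, seed = 300 + i)
    modulation_tests(unit_record("u", st, rep(100, length(st))),
                     trials)$p_value
  }, numeric(6)))
  rates <- colMeans(pvals < 0.05, na.rm = TRUE)
  # binomial 99% envelope around 0.05 for n = 150
  expect_true(all(rates < 0.05 + 3 * sqrt(0.05 * 0.95 / n_units)))
})

test_that("Fano factor matches hand arithmetic and the Poisson property", {
  # two qualifying trials with counts {1, 3}: mean 2, unbiased var 2, FF 1
  trials <- data.frame(
    trial = 1:2, stim_on = c(1, 10), contrast = c(1, 1),
    side = c("right", "right"), block_p_left = c(0.5, 0.5),
    first_move = c(1.2, 10.2), choice = c("right", "right"),
    feedback_type = c("reward", "reward"), feedback_time = c(1.5, 10.5),
    reaction_time = c(0.2, 0.2))
  st <- c(1.30, 10.25, 10.30, 10.35)  # 1 and 3 spikes in [fm+0.04, fm+0.2)
  u <- unit_record("ff", st, rep(100, 4))
  expect_equal(fano_factor(u, trials), 1.0)

  # identical counts give FF 0
  st0 <- c(1.30, 10.30)
  expect_equal(fano_factor(unit_record("c", st0, c(100, 100)), trials), 0)

  # fewer than 2 qualifying trials: undetermined
  one <- trials[1, ]
  expect_true(is.na(fano_factor(u, one)))

  # Poisson counts across 1000 trials: FF within 3 SE of 1
  n_tr <- 1000
  fm <- seq(10, by = 2, length.out = n_tr)
  big <- data.frame(
    trial = seq_len(n_tr), stim_on = fm - 0.3, contrast = 1,
    side = "right", block_p_left = 0.5, first_move = fm, choice = "right",
    feedback_type = "reward", feedback_time = fm + 0.3,
    reaction_time = 0.3)
  set.seed(31)
  counts <- rpois(n_tr, 4)
  st_big <- sort(unlist(lapply(seq_len(n_tr), function(i) {
    fm[i] + 0.04 + sort(runif(counts[i], 0, 0.1599))
  })))
  u_big <- unit_record("pois", st_big, rep(100, length(st_big)))
  ff <- fano_factor(u_big, big)
  se <- sqrt(2 / (n_tr - 1))
  expect_lt(abs(ff - 1), 3 * se)

  # invariant under trial reordering
  shuf <- big[sample(n_tr), ]
  expect_equal(fano_factor(u_big, shuf), ff)
})

test_that("session proportions respect the 4-unit region minimum", {
  trials <- gen_trial_table(150, seed = 40)
  dur <- max(trials$feedback_time) + 5
  make_unit <- function(id, modulated) {
    st <- gen_spike_train(5, dur, seed = 400 + id)
    if (modulated) {
      extra <- unlist(lapply(trials$first_move,
                             function(m) m + runif(3, 0, 0.2)))
      st <- sort(unique(c(st, extra)))
    }
    unit_record(paste0("u", id), st, rep(100, length(st)), region = "LP")
  }
  units <- lapply(1:10, function(i) make_unit(i, i <= 3))
  s <- quick_session(units, trials)
  tab <- proportion_modulated(list(s), "movement_initiation", "LP")
  expect_equal(nrow(tab), 1)
  expect_gte(tab$proportion, 0.3)  # the 3 injected responders
  expect_lte(tab$proportion, 0.6)

  s3 <- quick_session(units[1:3], trials)
  expect_null(proportion_modulated(list(s3), "movement_initiation", "LP"))
})
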