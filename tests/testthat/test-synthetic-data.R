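test_that("spike trains respect rate, refractoriness and contamination", {
  expect_length(gen_spike_train(0, 100, seed = 1), 0)

  st <- gen_spike_train(50, 120, refractory = 0.002, contamination = 0,
                        seed = 2)
  expect_true(all(diff(st) >= 0.002))
  expect_true(all(st >= 0 & st <= 120))
  expect_true(all(diff(st) > 0))
  # rate roughly preserved after thinning (50 sp/s, 2 ms dead time)
  expect_gt(length(st) / 120, 40)

  # ISI census on a contaminated train: contaminating spikes at fraction c
  # sit next to a neighbour within t_r with probability ~ 2 * t_r * rate,
  # so the fraction of short ISIs is about 2 * t_r * rate * c
  st_c <- gen_spike_train(20, 600, refractory = 0.002, contamination = 0.2,
                          seed = 3)
  frac <- mean(diff(st_c) < 0.002)
  expect_gt(frac, 0.008)
  expect_lt(frac, 0.035)
  expect_identical(mean(diff(gen_spike_train(20, 600, 0.002, 0, seed = 3))
                        < 0.002), 0)

  expect_error(gen_spike_train(-1, 10), "rate")
  expect_error(gen_spike_train(1, -10), "duration")
})

test_that("generators are deterministic in the seed and leave the RNG alone", {
  expect_identical(gen_spike_train(20, 60, seed = 5),
                   gen_spike_train(20, 60, seed = 5))
  expect_identical(gen_trial_table(100, seed = 5), gen_trial_table(100, seed = 5))
  set.seed(99)
  before <- .Random.seed
  invisible(gen_spike_train(20, 60, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("amplitude draws follow the Gaussian and truncation contract", {
  expect_length(gen_amplitudes(0, seed = 1), 0)
  a <- gen_amplitudes(10000, mean = 100, sd = 10, seed = 1)
  expect_lt(abs(mean(a) - 100), 3 * 10 / sqrt(10000))
  tr <- gen_amplitudes(10000, mean = 100, sd = 10, truncation = 100, seed = 1)
  expect_gte(min(tr), 100)
  expect_lt(abs(length(tr) / 10000 - 0.5), 0.03)
  expect_error(gen_amplitudes(-1), "n must")
})

test_that("trial tables carry block structure, contrasts and ordered events", {
  t1 <- gen_trial_table(1, seed = 1)
  expect_equal(nrow(t1), 1)
  expect_true(t1$stim_on < t1$first_move && t1$first_move < t1$feedback_time)

  tt <- gen_trial_table(3000, seed = 2)
  expect_true(all(tt$stim_on < tt$first_move))
  expect_true(all(tt$first_move < tt$feedback_time))
  expect_true(all(tt$reaction_time > 0))
  expect_true(all(tt$contrast %in% c(0, 0.0625, 0.125, 0.25, 1)))
  expect_setequal(unique(tt$block_p_left), c(0.5, 0.2, 0.8))
  # 80:20 block: right-side stimulus fraction ~ 0.8 within binomial error
  b <- tt[tt$block_p_left == 0.2, ]
  expect_lt(abs(mean(b$side == "right") - 0.8),
            4 * sqrt(0.8 * 0.2 / nrow(b)))
  # reaction times straddle the 0.15 s fast/slow split
  expect_gt(sum(tt$reaction_time < 0.15), 100)
  expect_gt(sum(tt$reaction_time > 0.15), 100)
})

test_that("multi-lab population preserves hierarchy bookkeeping", {
  pop <- small_population()
  expect_length(pop, 5 * 2)
  labs <- vapply(pop, function(s) s$lab_id, character(1))
  expect_equal(unname(table(labs)), rep(2L, 5), ignore_attr = TRUE)
  mice <- vapply(pop, function(s) s$subject_id, character(1))
  expect_length(unique(mice), 10)
  s <- pop[[1]]
  expect_length(s$units, 20)
  expect_equal(nrow(s$trial_table), 150)
  # all generated trains satisfy their construction constraints
  for (u in s$units) {
    expect_true(all(diff(u$spike_times) > 0))
    expect_length(u$amplitudes, length(u$spike_times))
  }
})

test_that("identical config gives identical population; lab effects shift it", {
  cfg <- synth_config(seed = 4, n_labs = 2, mice_per_lab = 1,
                      units_per_region = c("VISa/am" = 2, CA1 = 2, DG = 2,
                                           LP = 2, PO = 2), n_trials = 60)
  expect_identical(gen_multilab_population(cfg), gen_multilab_population(cfg))

  mean_rate <- function(pop, lab) {
    mean(unlist(lapply(pop[vapply(pop, function(s) s$lab_id,
                                  character(1)) == lab],
                       function(s) session_features(s)[["firing_rate"]])))
  }
  for (seed in 1:3) {
    shifted <- gen_multilab_population(synth_config(
      seed = seed, n_labs = 3, mice_per_lab = 2,
      units_per_region = c("VISa/am" = 3, CA1 = 3, DG = 3, LP = 3, PO = 3),
      n_trials = 80,
      lab_effects = list(lab_02 = list(firing_rate = 10))))
    rates <- vapply(c("lab_01", "lab_02", "lab_03"),
                    function(l) mean_rate(shifted, l), numeric(1))
    expect_equal(names(which.max(rates)), "lab_02")
  }
})

test_that("config validation and YAML round trip work", {
  expect_error(synth_config(contamination = 1.5), "contamination")
  expect_error(synth_config(refractory = 0), "refractory")
  expect_error(synth_config(n_trials = -1), "counts")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, n_labs = 3, n_trials = 120,
                        units_per_region = list(`VISa/am` = 2, CA1 = 2,
                                                DG = 2, LP = 2, PO = 2)),
                   path)
  cfg <- read_synth_config(path)
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$n_labs, 3L)
  expect_equal(cfg$units_per_region[["CA1"]], 2)
  expect_error(read_synth_config(tempfile()), "not found")
})
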