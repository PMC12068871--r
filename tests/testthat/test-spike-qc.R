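# Brute-force Poisson survival by term-wise summation, the independent
# oracle for the sliding refractory-period confidence (valid for small
# lambda).
brute_pois_survival <- function(k, lambda) {
  1 - sum(exp(-lambda) * lambda^(0:k) / factorial(0:k))
}

test_that("sliding RP confidence matches closed-form hand examples", {
  # 36,000 spikes over 3600 s with no ISI below 10 ms
  st <- seq(0.1, by = 0.1, length.out = 36000)
  res <- sliding_rp_confidence(st, 3600)
  i2ms <- which.min(abs(res$rp_grid - 0.002))
  lam <- 2 * res$rp_grid[i2ms] * 0.1 * 36000 * 10
  expect_equal(res$confidence_per_rp[i2ms], 1 - exp(-lam), tolerance = 1e-12)
  expect_gt(res$max_confidence, 0.999)
  expect_true(res$pass)

  # 10 spikes over 10 s, zero violations: too few spikes to be confident
  st10 <- seq(0.5, by = 1, length.out = 10)
  res10 <- sliding_rp_confidence(st10, 10)
  expect_equal(max(res10$confidence_per_rp), 1 - exp(-0.02),
               tolerance = 1e-10)
  expect_false(res10$pass)
})

test_that("confidence equals brute-force Poisson-CDF summation", {
  set.seed(7)
  for (i in 1:10) {
    st <- gen_spike_train(5, 60, contamination = 0.1, seed = i)
    res <- sliding_rp_confidence(st, 60)
    isis <- diff(st)
    n <- length(st)
    for (j in seq(1, 50, by = 7)) {
      tr <- res$rp_grid[j]
      lam <- 2 * tr * 0.1 * n * (n / 60)
      if (lam < 30) {
        expect_lt(abs(res$confidence_per_rp[j] -
                        brute_pois_survival(sum(isis < tr), lam)), 1e-10)
      }
    }
  }
})

test_that("adding refractory-period violations never raises the confidence", {
  st <- gen_spike_train(20, 300, contamination = 0, seed = 3)
  base <- sliding_rp_confidence(st, 300)$max_confidence
  prev <- base
  for (n_bad in c(5, 20, 80)) {
    bad <- st[seq(10, by = 3, length.out = n_bad)] + 0.0012
    cur <- sliding_rp_confidence(sort(unique(c(st, bad))),
                                 300)$max_confidence
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("RP metric is calibrated on contaminated and clean trains", {
  pass_at <- function(contam, n_seeds = 20) {
    mean(vapply(seq_len(n_seeds), function(i) {
      st <- gen_spike_train(20, 600, contamination = contam, seed = 100 + i)
      sliding_rp_confidence(st, 600)$pass
    }, logical(1)))
  }
  expect_gte(pass_at(0), 0.95)
  expect_lte(pass_at(0.2), 0.05)
  expect_lte(pass_at(0.5), 0.05)
})

test_that("RP metric reports degenerate inputs as failures with reasons", {
  res <- sliding_rp_confidence(numeric(0), 10)
  expect_false(res$pass)
  expect_equal(res$reason, "insufficient spikes")
  expect_false(sliding_rp_confidence(c(1), 10)$pass)
})

test_that("amplitude cutoff separates truncated from untruncated units", {
  pass_rate <- function(truncation, n_seeds = 20) {
    mean(vapply(seq_len(n_seeds), function(i) {
      a <- gen_amplitudes(10000, 100, 10, truncation = truncation,
                          seed = 200 + i)
      amplitude_cutoff(a)$pass
    }, logical(1)))
  }
  expect_gte(pass_rate(NULL), 0.95)
  expect_lte(pass_rate(100), 0.05)
})

test_that("amplitude cutoff is scale invariant and guards degenerate input", {
  a <- gen_amplitudes(5000, 100, 10, seed = 5)
  r1 <- amplitude_cutoff(a)
  r2 <- amplitude_cutoff(a * 3.7)
  expect_equal(r1$sd_distance, r2$sd_distance, tolerance = 1e-12)
  expect_equal(r1$low_bin_fraction, r2$low_bin_fraction, tolerance = 1e-12)

  expect_equal(amplitude_cutoff(rep(80, 100))$reason,
               "degenerate distribution")
  expect_equal(amplitude_cutoff(rnorm(10, 100))$reason,
               "insufficient spikes")
})

test_that("median amplitude criterion uses a strict threshold", {
  expect_true(median_amplitude_pass(c(55, 60, 65))$pass)
  expect_false(median_amplitude_pass(rep(50, 5))$pass)
  expect_false(median_amplitude_pass(c(48, 49, 50))$pass)
  expect_false(median_amplitude_pass(numeric(0))$pass)
})

test_that("unit_qc aggregates the three metrics with per-criterion detail", {
  dur <- 600
  st <- gen_spike_train(20, dur, seed = 9)
  clean <- unit_record("ok", st,
                       gen_amplitudes(length(st), 100, 10, seed = 9),
                       region = "LP")
  rep_clean <- unit_qc(clean, dur)
  expect_true(rep_clean$pass)

  dim_unit <- clean
  dim_unit$amplitudes <- clean$amplitudes * 0.3  # mean ~30 uV
  rep_dim <- unit_qc(dim_unit, dur)
  expect_false(rep_dim$pass)
  failed <- rep_dim$criteria$criterion[!rep_dim$criteria$pass]
  expect_equal(failed, "median_amplitude")

  empty <- unit_record("empty", numeric(0), numeric(0))
  rep_empty <- unit_qc(empty, dur)
  expect_false(rep_empty$pass)
  expect_true(all(!rep_empty$criteria$pass))
  expect_true(any(grepl("insufficient", rep_empty$criteria$reason)))
})
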