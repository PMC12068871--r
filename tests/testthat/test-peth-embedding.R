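test_that("PETH normalization behaves at the baseline and for silent baselines", {
  trials <- gen_trial_table(200, seed = 51)
  dur <- max(trials$feedback_time) + 5
  # perfectly regular 50 sp/s unit: every 20 ms bin holds exactly 1 spike,
  # so the normalized double PETH is identically zero
  const <- regular_unit(rate = 50, duration = dur)
  s <- quick_session(list(const), trials)
  pm <- build_peth_matrix(list(s))
  expect_equal(nrow(pm$Y), 1)
  expect_equal(ncol(pm$Y), 200)
  expect_true(all(abs(pm$Y) < 1e-9))
  expect_true(all(is.finite(pm$Y)))

  # silent baseline, active post-movement at r sp/s: post bins ~ r / eps
  r <- 10
  st <- sort(unlist(lapply(trials$first_move,
                           function(m) m + sort(runif(r, 0, 1)))))
  act <- unit_record("act", unique(st), rep(100, length(unique(st))))
  pm2 <- build_peth_matrix(list(quick_session(list(act), trials)))
  post <- pm2$bin_centers > 0.1 & pm2$bin_centers < 0.9
  expect_equal(mean(pm2$Y[1, c(post, post)]), r / pm2$eps, tolerance = 0.25)

  # rt threshold below all RTs: every cell lacks a fast trial
  expect_error(build_peth_matrix(list(s), rt_threshold = 1e-6), "no cells")
})

test_that("PCA embedding is exact on low-rank input and matches an oracle", {
  set.seed(52)
  # rank-1 matrix: r2 = 1 for every cell at k = 1
  u <- rnorm(30)
  v <- rnorm(50)
  Y1 <- outer(u, v)
  emb1 <- pca_embed(Y1, k = 1)
  expect_equal(emb1$r2_per_cell, rep(1, 30), tolerance = 1e-10)

  # full rank k: perfect reconstruction
  Y <- matrix(rnorm(20 * 12), 20, 12)
  embf <- pca_embed(Y, k = 12)
  expect_equal(embf$r2_per_cell, rep(1, 20), tolerance = 1e-8)

  # independent oracle: eigendecomposition of the covariance matrix
  Y2 <- outer(rnorm(100), rnorm(40)) + outer(rnorm(100), rnorm(40)) +
    matrix(rnorm(100 * 40, 0, 0.01), 100, 40)
  emb <- pca_embed(Y2, k = 2)
  Xc <- sweep(Y2, 2, colMeans(Y2))
  eig <- eigen(crossprod(Xc), symmetric = TRUE)
  oracle_recon <- Xc %*% eig$vectors[, 1:2] %*% t(eig$vectors[, 1:2])
  own_recon <- emb$U %*% emb$V
  expect_equal(own_recon, oracle_recon, tolerance = 1e-8,
               ignore_attr = TRUE)
  # true components recovered: residual of V rows off the plane ~ 0
  expect_equal(emb$d[1:2]^2, eig$values[1:2], tolerance = 1e-8)
  # V rows orthogonal
  expect_equal(sum(emb$V[1, ] * emb$V[2, ]), 0, tolerance = 1e-10)

  expect_error(pca_embed(Y[1, , drop = FALSE], k = 2), "k = 2")
})

test_that("embedding respects row permutations and r2 grows with k", {
  set.seed(53)
  Y <- matrix(rnorm(40 * 30), 40, 30) + outer(rnorm(40), rnorm(30))
  emb <- pca_embed(Y, k = 2)
  perm <- sample(40)
  emb_p <- pca_embed(Y[perm, ], k = 2)
  # scores permute with the rows (up to global sign per component)
  agree <- vapply(1:2, function(j) {
    min(max(abs(emb_p$U[, j] - emb$U[perm, j])),
        max(abs(emb_p$U[, j] + emb$U[perm, j])))
  }, numeric(1))
  expect_true(all(agree < 1e-8))
  r2k <- vapply(1:4, function(k) mean(pca_embed(Y, k = k)$r2_per_cell),
                numeric(1))
  expect_true(all(diff(r2k) > 0))
})

test_that("region KS tests fire on synthetic templates while lab tests do not", {
  pop <- small_population(seed = 61, n_labs = 5, mice_per_lab = 3,
                          n_trials = 150)
  pm <- build_peth_matrix(pop)
  emb <- pca_embed(pm, k = 2)
  regions <- sort(unique(pm$cell_meta$region))
  region_p <- vapply(regions, function(r) {
    ks_target_test(emb$U[, 1], pm$cell_meta$region == r,
                   n_comparisons = 5)$p_value
  }, numeric(1))
  labs <- sort(unique(pm$cell_meta$lab))
  lab_p <- vapply(labs, function(l) {
    ks_target_test(emb$U[, 1], pm$cell_meta$lab == l,
                   n_comparisons = 5)$p_value
  }, numeric(1))
  expect_true(all(region_p < 0.01 / 5))
  expect_lte(sum(lab_p < 0.01 / 5), 1)
})

test_that("KS target test guards degenerate masks and detects separation", {
  x <- c(rnorm(50), rnorm(50, 100))
  res <- ks_target_test(x, rep(c(TRUE, FALSE), each = 50))
  expect_equal(res$statistic, 1.0)
  expect_true(res$significant)
  expect_error(ks_target_test(x, rep(TRUE, 100)), "non-empty")
  expect_error(ks_target_test(x, rep(FALSE, 100)), "non-empty")
})

test_that("2D distance permutation test calibrates and detects displacement", {
  set.seed(54)
  U <- matrix(rnorm(120 * 2), ncol = 2)
  labels <- rep(c("a", "b", "c"), each = 40)
  res0 <- distance_permutation_test(U, labels, n_perm = 400, seed = 55)
  expect_true(all(res0$p_value > 0.01))

  U2 <- U
  U2[labels == "b", ] <- U2[labels == "b", ] + 5
  res1 <- distance_permutation_test(U2, labels, n_perm = 400, seed = 56)
  expect_equal(res1$p_value[res1$group == "b"], 1 / 401)

  expect_error(distance_permutation_test(U, labels, n_perm = 0), "n_perm")
  expect_error(distance_permutation_test(U[, 1, drop = FALSE], labels),
               "2 columns")
})

test_that("Fisher combination matches the closed-form chi-square survival", {
  # df = 4: survival S(x) = exp(-x/2) * (1 + x/2)
  X <- -2 * (log(0.05) + log(0.05))
  expect_equal(X, 11.98293, tolerance = 1e-5)
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$p_value, exp(-X / 2) * (1 + X / 2), tolerance = 1e-10)
  expect_lt(abs(res$p_value - 0.0175), 1e-4)
  expect_equal(fisher_combine(c(1, 1, 1))$p_value, 1)
  expect_error(fisher_combine(c(0.5, 0)), "p-values")
})

test_that("subsampled KS with Fisher combination handles sizes and nulls", {
  set.seed(57)
  x <- c(rnorm(100), rnorm(30, 4))
  mask <- rep(c(FALSE, TRUE), c(100, 30))
  res <- subsampled_ks_fisher(x, mask, n_samplings = 50, seed = 58)
  expect_lt(res$combined_p, 1e-6)
  expect_length(res$p_values, 50)

  # identical multisets on both sides: every subsampled p is 1
  y <- c(1:5, 1:5)
  m <- rep(c(TRUE, FALSE), each = 5)
  res1 <- subsampled_ks_fisher(y, m, n_samplings = 10, seed = 59)
  expect_equal(res1$combined_p, 1)

  expect_equal(subsampled_ks_fisher(c(1, 2, 3), c(TRUE, FALSE, FALSE),
                                    seed = 1)$combined_p, NA_real_)
})
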