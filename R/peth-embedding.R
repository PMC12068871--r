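#' Build the double-PETH matrix across sessions
#'
#' For every cell, two peri-event time histograms aligned to first-movement
#' onset are computed — one averaging fast-reaction-time trials
#' (`rt < rt_threshold`), one averaging slow ones (`rt > rt_threshold`) —
#' each with `T = (t_range[2]-t_range[1])/bin` bins (default T = 100 bins
#' of 20 ms spanning -0.5 to 1.5 s). Each PETH is normalized as
#' `(PETH - b) / (b + eps)` where `b` is the cell's mean pre-movement
#' baseline rate and `eps` a small positive offset that avoids amplifying
#' noise in near-silent cells. The two normalized PETHs are concatenated
#' into one row of the N x 2T matrix `Y`. Cells lacking a fast or a slow
#' trial are excluded and counted.
#'
#' @param sessions list of [session_record()] objects.
#' @param rt_threshold fast/slow reaction-time split, s (default 0.15).
#' @param bin bin width, s (default 0.02).
#' @param t_range window around movement onset, s (default `c(-0.5, 1.5)`,
#'   half-open bins tiling it).
#' @param baseline_window pre-movement window defining the baseline rate, s
#'   (default `c(-0.5, -0.2)`).
#' @param eps baseline offset, spikes/s (default 0.5).
#' @return an object of class `peth_matrix`: `Y` (N x 2T), `cell_meta`
#'   (data.frame with `lab`, `region`, `session`, `unit_id` per row),
#'   `bin_centers`, `rt_split`, `baseline_window`, `eps`, `n_excluded`.
#' @export
build_peth_matrix <- function(sessions, rt_threshold = 0.15, bin = 0.02,
                              t_range = c(-0.5, 1.5),
                              baseline_window = c(-0.5, -0.2), eps = 0.5) {
  n_bins <- round(diff(t_range) / bin)
  edges <- t_range[1] + bin * (0:n_bins)
  centers <- edges[-1] - bin / 2
  base_bins <- centers >= baseline_window[1] & centers < baseline_window[2]
  if (!any(base_bins)) stop_invalid("baseline window outside PETH range")

  rows <- list()
  meta <- list()
  n_excluded <- 0L
  for (s in sessions) {
    tr <- s$trial_table
    fast <- tr$first_move[tr$reaction_time < rt_threshold]
    slow <- tr$first_move[tr$reaction_time > rt_threshold]
    for (u in s$units) {
      if (!length(fast) || !length(slow)) {
        n_excluded <- n_excluded + 1L
        next
      }
      pf <- peth(u$spike_times, fast, edges, bin)
      ps <- peth(u$spike_times, slow, edges, bin)
      b <- mean(c(peth_baseline(pf, base_bins, length(fast)),
                  peth_baseline(ps, base_bins, length(slow))))
      row <- c((pf - b) / (b + eps), (ps - b) / (b + eps))
      rows[[length(rows) + 1L]] <- row
      meta[[length(meta) + 1L]] <- data.frame(
        lab = s$lab_id, region = u$region, session = s$session_id,
        unit_id = u$unit_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop_invalid("no cells with both fast and slow trials")
  structure(list(Y = do.call(rbind, rows), cell_meta = do.call(rbind, meta),
                 bin_centers = centers, rt_split = rt_threshold,
                 baseline_window = baseline_window, eps = eps,
                 n_excluded = n_excluded),
            class = "peth_matrix")
}

# trial-averaged binned firing rate around the aligning events
peth <- function(spike_times, events, edges, bin) {
  counts <- numeric(length(edges) - 1L)
  for (ev in events) {
    rel <- spike_times[spike_times >= ev + edges[1] &
                         spike_times < ev + edges[length(edges)]] - ev
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges),
                                  nbins = length(edges) - 1L)
  }
  counts / (length(events) * bin)
}

peth_baseline <- function(p, base_bins, n_trials) mean(p[base_bins])

#' @export
print.peth_matrix <- function(x, ...) {
  cat(sprintf("PETH matrix: %d cells x %d bins (2 x T), %d cell(s) excluded\n",
              nrow(x$Y), ncol(x$Y), x$n_excluded))
  cat(sprintf("  regions: %s\n",
              paste(names(table(x$cell_meta$region)), collapse = ", ")))
  invisible(x)
}

#' PCA embedding of the double-PETH matrix
#'
#' Mean-centered truncated singular value decomposition: the k-dimensional
#' scores of each cell (`U`, N x k) and the k temporal basis functions
#' (`V`, k x 2T) give the low-rank approximation `U V + column means ~ Y`.
#' The per-cell goodness of fit is
#' `r2 = 1 - ||row - reconstruction||^2 / ||row - mean(row)||^2`.
#'
#' @param Y numeric matrix (N x 2T), or a `peth_matrix`.
#' @param k embedding dimension (default 2; requires N >= k).
#' @param center subtract column means before the SVD (default TRUE; set
#'   FALSE for an uncentered SVD).
#' @return an object of class `peth_embedding`: `U` (N x k scores), `V`
#'   (k x 2T), `d` (singular values), `r2_per_cell`, `k`, `col_means`,
#'   and `cell_meta` when a `peth_matrix` was supplied.
#' @export
pca_embed <- function(Y, k = 2L, center = TRUE) {
  meta <- NULL
  if (inherits(Y, "peth_matrix")) {
    meta <- Y$cell_meta
    Y <- Y$Y
  }
  Y <- as.matrix(Y)
  if (nrow(Y) < k) stop_invalid("need at least k = %d rows", k)
  cm <- if (center) colMeans(Y) else rep(0, ncol(Y))
  Xc <- sweep(Y, 2L, cm)
  sv <- svd(Xc, nu = k, nv = k)
  U <- sv$u %*% diag(sv$d[seq_len(k)], k)
  V <- t(sv$v)
  recon <- sweep(U %*% V, 2L, cm, `+`)
  res <- rowSums((Y - recon)^2)
  tot <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(tot > 0, 1 - res / tot, ifelse(res < 1e-12, 1, NA_real_))
  structure(list(U = U, V = V, d = sv$d, r2_per_cell = r2, k = k,
                 col_means = cm, cell_meta = meta),
            class = "peth_embedding")
}

#' @export
print.peth_embedding <- function(x, ...) {
  cat(sprintf("PETH embedding: %d cells, k = %d; median r2 = %.3f\n",
              nrow(x$U), x$k, median(x$r2_per_cell)))
  invisible(x)
}

#' KS test of a target subset's first-PC distribution against the rest
#'
#' Two-sample Kolmogorov-Smirnov test comparing the first principal
#' component values of a target subset of cells (a lab or a region) with
#' those of all remaining cells. Significance is assessed at `alpha` with a
#' Bonferroni correction over `n_comparisons` (the number of regions, by
#' the convention used for these tests — not the number of tests).
#'
#' @param pc1_values first-PC value per cell.
#' @param target_mask logical; TRUE for the target subset. Both groups must
#'   be non-empty.
#' @param alpha base significance level (default 0.01).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return list with `statistic`, `p_value`, `significant`.
#' @export
ks_target_test <- function(pc1_values, target_mask, alpha = 0.01,
                           n_comparisons = 1L) {
  if (!any(target_mask) || all(target_mask))
    stop_invalid("both target and remainder must be non-empty")
  kt <- suppressWarnings(ks.test(pc1_values[target_mask],
                                 pc1_values[!target_mask]))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha / n_comparisons)
}

#' 2D-distance permutation test in the embedding plane
#'
#' For each group, the observed statistic is the Euclidean distance between
#' the group's mean embedded activity and the mean of all remaining cells
#' in the first two principal components; the null is built by shuffling
#' group labels, and p-values use the add-one estimator.
#'
#' @param U2d numeric matrix (N x 2) of embedding scores.
#' @param labels group identifier per row (>= 2 groups).
#' @param n_perm number of label shuffles (> 0).
#' @param seed optional integer seed (local to this call).
#' @return data.frame with one row per group: `group`, `distance`,
#'   `p_value`.
#' @export
distance_permutation_test <- function(U2d, labels, n_perm = 1000L,
                                      seed = NULL) {
  U2d <- as.matrix(U2d)
  if (ncol(U2d) != 2L) stop_invalid("U2d must have 2 columns")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop_invalid("need at least 2 groups")

  group_dist <- function(lab, g) {
    ing <- lab == g
    sqrt(sum((colMeans(U2d[ing, , drop = FALSE]) -
                colMeans(U2d[!ing, , drop = FALSE]))^2))
  }
  obs <- vapply(groups, function(g) group_dist(labels, g), numeric(1))
  exceed <- setNames(integer(length(groups)), groups)
  local_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample(labels)
      for (g in groups) {
        if (group_dist(perm, g) >= obs[[g]])
          exceed[[g]] <- exceed[[g]] + 1L
      }
    }
  })
  data.frame(group = groups, distance = unname(obs),
             p_value = unname((1 + exceed) / (1 + n_perm)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 sum(log p)` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' fisher_combine(c(0.05, 0.05))$p_value  # ~0.0175
#' @export
fisher_combine <- function(p) {
  if (!length(p) || any(p <= 0 | p > 1))
    stop_invalid("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  list(statistic = X, df = 2L * length(p),
       p_value = pchisq(X, df = 2 * length(p), lower.tail = FALSE))
}

#' Cell-number-controlled KS test via subsampling and Fisher combination
#'
#' Controls for unequal group sizes: repeatedly draws the minimum group
#' size from each side without replacement, runs the two-sample KS test on
#' the subsamples, and combines the collected p-values with Fisher's
#' method (chi-square, `2 * n_samplings` df). Because subsamples overlap,
#' the combined p-value is not guaranteed to be uniformly distributed
#' under the null; its calibration is measured empirically in the package
#' tests rather than assumed.
#'
#' @param pc1_values first-PC value per cell.
#' @param target_mask logical target-subset mask.
#' @param n_samplings number of subsampling rounds (default 100).
#' @param seed optional integer seed (local to this call).
#' @return list with `combined_p`, `statistic`, `df`, `p_values`; or, when
#'   the smaller group has fewer than 2 cells, `combined_p = NA` with a
#'   `reason`.
#' @export
subsampled_ks_fisher <- function(pc1_values, target_mask, n_samplings = 100L,
                                 seed = NULL) {
  if (!any(target_mask) || all(target_mask))
    stop_invalid("both target and remainder must be non-empty")
  a <- pc1_values[target_mask]
  b <- pc1_values[!target_mask]
  m <- min(length(a), length(b))
  if (m < 2L)
    return(list(combined_p = NA_real_, reason = "fewer than 2 cells"))
  ps <- local_seed(seed, {
    vapply(seq_len(n_samplings), function(i) {
      suppressWarnings(ks.test(sample(a, m), sample(b, m))$p.value)
    }, numeric(1))
  })
  fc <- fisher_combine(pmax(ps, .Machine$double.xmin))
  list(combined_p = fc$p_value, statistic = fc$statistic, df = fc$df,
       p_values = ps)
}
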