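#' Max-CDF-distance statistic across laboratories
#'
#' For each lab, the largest absolute difference between the empirical CDF
#' of the lab's values and the empirical CDF of all remaining values,
#' evaluated over the pooled sample points (the two-sample KS statistic of
#' lab vs rest); the statistic is the maximum over labs — the deviation of
#' the lab that deviates most.
#'
#' @param values numeric feature values.
#' @param labels lab identifier per value; at least 2 labs, each non-empty.
#' @return the statistic, in \[0, 1\].
#' @examples
#' max_cdf_distance(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # 1
#' max_cdf_distance(c(1, 3, 2, 4), c("A", "A", "B", "B"))  # 0.5
#' @export
max_cdf_distance <- function(values, labels) {
  labels <- as.character(labels)
  if (length(values) != length(labels))
    stop_invalid("values and labels must have equal length")
  labs <- unique(labels)
  if (length(labs) < 2L) stop_invalid("need at least 2 labs")
  ord <- order(values)
  max_cdf_stat(labels[ord], labs, valid_eval_points(values[ord]))
}

# evaluation points of the pooled step CDFs: ends of tied runs
valid_eval_points <- function(sorted_values) {
  c(diff(sorted_values) > 0, TRUE)
}

# core statistic on pre-sorted labels; shared with the permutation loop
max_cdf_stat <- function(sorted_labels, labs, valid) {
  n <- length(sorted_labels)
  idx <- seq_len(n)
  stat <- 0
  for (lab in labs) {
    ind <- sorted_labels == lab
    nl <- sum(ind)
    if (nl == 0L || nl == n) stop_invalid("each lab must be non-empty")
    cum <- cumsum(ind)
    d <- abs(cum / nl - (idx - cum) / (n - nl))
    m <- max(d[valid])
    if (m > stat) stat <- m
  }
  stat
}

#' Permutation test for across-lab differences
#'
#' Tests the null hypothesis that the assignment of mice to laboratories is
#' completely random, using the max-CDF-distance statistic. The null
#' distribution is sampled by permuting the mouse-to-lab assignment
#' (leaving the number of mice per laboratory intact) `n_perm` times; when
#' each observation is its own unit, this reduces to permuting value
#' labels. The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` (never exactly zero;
#' within 1/n_perm of the plain proportion of more-extreme null values).
#'
#' @param values numeric feature values (one per neuron, session or mouse).
#' @param labels lab identifier per value.
#' @param mouse optional mouse identifier per value; values of one mouse
#'   stay together under relabelling. Default: each value is its own unit.
#' @param n_perm number of random relabellings (default 50000).
#' @param seed optional integer seed (local to this call).
#' @param alpha significance level for the `significant` flag
#'   (default 0.01).
#' @return an object of class `permutation_result`: `statistic`,
#'   `null_statistics`, `p_value`, `n_perm`, `seed`, `group_sizes`,
#'   `alpha`, `significant`.
#' @export
permutation_test <- function(values, labels, mouse = NULL, n_perm = 50000L,
                             seed = NULL, alpha = 0.01) {
  labels <- as.character(labels)
  if (is.null(mouse)) mouse <- seq_along(values)
  if (length(mouse) != length(values))
    stop_invalid("mouse must match values in length")
  mouse <- as.character(mouse)
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")

  mice <- unique(mouse)
  mouse_lab <- vapply(mice, function(m) {
    l <- unique(labels[mouse == m])
    if (length(l) != 1L) stop_invalid("mouse %s spans several labs", m)
    l
  }, character(1))
  labs <- unique(labels)
  if (length(labs) < 2L) stop_invalid("need at least 2 labs")

  ord <- order(values)
  valid <- valid_eval_points(values[ord])
  mouse_idx_sorted <- match(mouse[ord], mice)
  observed <- max_cdf_stat(labels[ord], labs, valid)

  null_stats <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      new_lab <- mouse_lab[sample.int(length(mice))]
      max_cdf_stat(new_lab[mouse_idx_sorted], labs, valid)
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (1 + n_perm)
  structure(list(statistic = observed, null_statistics = null_stats,
                 p_value = p, n_perm = as.integer(n_perm), seed = seed,
                 group_sizes = table(labels), alpha = alpha,
                 significant = p < alpha),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Across-lab permutation test (max-CDF distance)\n"))
  cat(sprintf("  statistic = %.4f, p = %.4g (%d permutations)%s\n",
              x$statistic, x$p_value, x$n_perm,
              if (x$significant) sprintf("  [significant at %.3g]", x$alpha)
              else ""))
  invisible(x)
}

#' Power analysis: smallest lab shift that makes the test significant
#'
#' Shifts all of one lab's values up (and, separately, down) by an additive
#' amount and uses binary search to find the smallest magnitude at which
#' the permutation test becomes significant (p < alpha), holding the other
#' labs fixed. The permutation null is frozen (same relabellings, derived
#' from `seed`, at every candidate shift) so the search is well defined;
#' the returned shift satisfies `p(shift) < alpha` and
#' `p(shift - tol * sign(shift)) >= alpha`.
#'
#' @param values,labels,mouse as in [permutation_test()].
#' @param target_lab the lab whose values are shifted.
#' @param alpha significance level (default 0.01).
#' @param tol search tolerance in feature units (default 0.1% of the pooled
#'   value range).
#' @param n_perm permutations of the frozen null (default 1000).
#' @param seed integer seed for the frozen null (default 1).
#' @param max_iter maximum bisection iterations per direction (default 20).
#' @return list with `shift_up` (>= 0), `shift_down` (<= 0), `p_zero`, and
#'   `flagged` (`"already significant"` when p(0) < alpha, in which case
#'   both shifts are 0; `"no significant shift found"` if the bracket could
#'   not be expanded to significance).
#' @export
power_shift <- function(values, labels, target_lab, mouse = NULL,
                        alpha = 0.01, tol = NULL, n_perm = 1000L, seed = 1L,
                        max_iter = 20L) {
  labels <- as.character(labels)
  if (!target_lab %in% labels) stop_invalid("unknown target lab")
  if (is.null(tol)) tol <- 0.001 * diff(range(values))
  if (tol <= 0) stop_invalid("tol must be > 0")
  if (is.null(mouse)) mouse <- seq_along(values)
  mouse <- as.character(mouse)
  mice <- unique(mouse)
  mouse_lab <- vapply(mice, function(m) unique(labels[mouse == m])[1],
                      character(1))
  labs <- unique(labels)
  # frozen relabellings
  perms <- local_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(length(mice)))
  })
  target <- labels == target_lab

  p_at <- function(shift) {
    v <- values + shift * target
    ord <- order(v)
    valid <- valid_eval_points(v[ord])
    mi <- match(mouse[ord], mice)
    obs <- max_cdf_stat(labels[ord], labs, valid)
    null_ge <- vapply(perms, function(pm) {
      max_cdf_stat(mouse_lab[pm][mi], labs, valid) >= obs
    }, logical(1))
    (1 + sum(null_ge)) / (1 + n_perm)
  }

  p0 <- p_at(0)
  if (p0 < alpha)
    return(list(shift_up = 0, shift_down = 0, p_zero = p0,
                flagged = "already significant"))

  search_dir <- function(sign) {
    step <- max(sd(values), tol)
    hi <- sign * step
    expansions <- 0L
    while (p_at(hi) >= alpha) {
      hi <- 2 * hi
      expansions <- expansions + 1L
      if (expansions > 40L) return(NA_real_)
    }
    lo <- 0
    iter <- 0L
    while (abs(hi - lo) > tol && iter < max_iter) {
      mid <- (hi + lo) / 2
      if (p_at(mid) < alpha) hi <- mid else lo <- mid
      iter <- iter + 1L
    }
    # defining property holds by the bisection invariant when the gap
    # closed below tol; nudge down if p is locally non-monotone
    guard <- 0L
    while (p_at(hi - sign * tol) < alpha && guard < 50L) {
      hi <- hi - sign * tol
      guard <- guard + 1L
    }
    hi
  }

  up <- search_dir(1)
  down <- search_dir(-1)
  list(shift_up = up, shift_down = down, p_zero = p0,
       flagged = if (anyNA(c(up, down))) "no significant shift found"
       else NULL)
}

#' Lab decoding with a label-shuffle null
#'
#' Trains a random-forest classifier to predict the group (lab or region)
#' of each recording from its electrophysiological features, scored by
#' stratified cross-validated accuracy; the null distribution is the same
#' accuracy on label-shuffled data, and the p-value is the fraction of
#' shuffles whose accuracy is at least the observed one.
#'
#' @param features data.frame or matrix, one row per recording (typically
#'   the five markers of [session_features()]).
#' @param labels group identifier per row.
#' @param n_shuffles label shuffles for the null (default 500).
#' @param seed optional integer seed (local to this call).
#' @param n_trees random-forest size (default 200).
#' @param n_folds cross-validation folds (default 5, reduced to the
#'   smallest class size if needed).
#' @return list with `accuracy`, `null_accuracies`, `p_value`, `classes`.
#' @export
decode_group_null <- function(features, labels, n_shuffles = 500L,
                              seed = NULL, n_trees = 200L, n_folds = 5L) {
  features <- as.data.frame(features)
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("dropping classes with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    features <- features[keep, , drop = FALSE]
    labels <- labels[keep]
    sizes <- table(labels)
  }
  if (length(sizes) < 2L) stop_invalid("need at least 2 classes")
  k <- max(2L, min(n_folds, min(sizes)))

  local_seed(seed, {
    cv_accuracy <- function(y) {
      y <- factor(y)
      folds <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
      correct <- logical(length(y))
      for (f in seq_len(k)) {
        test <- folds == f
        fit <- randomForest::randomForest(
          x = features[!test, , drop = FALSE], y = droplevels(y[!test]),
          ntree = n_trees)
        pred <- predict(fit, features[test, , drop = FALSE])
        correct[test] <- as.character(pred) == as.character(y[test])
      }
      mean(correct)
    }
    acc <- cv_accuracy(labels)
    null_acc <- vapply(seq_len(n_shuffles),
                       function(i) cv_accuracy(sample(labels)), numeric(1))
    list(accuracy = acc, null_accuracies = null_acc,
         p_value = mean(null_acc >= acc), classes = names(sizes))
  })
}
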