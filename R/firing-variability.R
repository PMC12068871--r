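#' Per-neuron feature table for variability analyses
#'
#' One row per unit: spatial position, waveform features and
#' session-averaged firing rate, ready for [find_outliers()],
#' [compare_feature_distributions()] and [variance_regression()].
#'
#' @param sessions list of [session_record()] objects.
#' @param region optional region label to restrict to.
#' @return data.frame with columns `lab_id`, `session_id`, `unit_id`,
#'   `region`, `x`, `y`, `z` (um), `amplitude` (uV, median per unit),
#'   `ptt_duration` (ms), `session_mean_rate` (spikes/s).
#' @export
feature_table <- function(sessions, region = NULL) {
  rows <- lapply(sessions, function(s) {
    dur <- session_duration(s)
    do.call(rbind, lapply(s$units, function(u) {
      data.frame(lab_id = s$lab_id, session_id = s$session_id,
                 unit_id = u$unit_id, region = u$region,
                 x = u$position[1], y = u$position[2], z = u$position[3],
                 amplitude = if (length(u$amplitudes))
                   median(u$amplitudes) else NA_real_,
                 ptt_duration = u$ptt_duration,
                 session_mean_rate = length(u$spike_times) / dur,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(region)) tab <- tab[tab$region == region, , drop = FALSE]
  tab
}

#' Identify outlier neurons by firing rate
#'
#' A neuron is an outlier when its absolute deviation from the median
#' firing rate exceeds `frac` of the firing rate range (max - min), the
#' range being taken over the pooled neurons supplied. The rule is
#' scale-equivariant: rescaling all rates leaves the mask unchanged. A
#' zero range yields an all-FALSE mask.
#'
#' @param rates session-averaged firing rates, spikes/s (>= 2 values).
#' @param frac fraction of the range (default 0.15).
#' @return logical outlier mask.
#' @examples
#' find_outliers(c(0:9, 100))  # only the 100 sp/s neuron
#' @export
find_outliers <- function(rates, frac = 0.15) {
  if (length(rates) < 2L) stop_invalid("need >= 2 neurons")
  rng <- diff(range(rates))
  if (rng == 0) return(rep(FALSE, length(rates)))
  abs(rates - median(rates)) > frac * rng
}

#' Compare feature distributions between two groups of neurons
#'
#' Two-sample Kolmogorov-Smirnov test per feature (by default the five
#' regression features), with Bonferroni correction over the number of
#' features compared. Degenerate features (a group with < 2 values) are
#' reported as undetermined.
#'
#' @param table a [feature_table()].
#' @param mask logical group mask (e.g. from [find_outliers()] or a
#'   task-modulation flag).
#' @param features columns to compare (default x, y, z, amplitude,
#'   ptt_duration).
#' @param alpha base significance level (default 0.05).
#' @return data.frame with one row per feature: `feature`, `statistic`,
#'   `p_value`, `p_corrected` (Bonferroni), `significant`.
#' @export
compare_feature_distributions <- function(table, mask,
                                          features = c("x", "y", "z",
                                                       "amplitude",
                                                       "ptt_duration"),
                                          alpha = 0.05) {
  stopifnot(length(mask) == nrow(table))
  rows <- lapply(features, function(f) {
    a <- table[[f]][mask]
    b <- table[[f]][!mask]
    if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) {
      return(data.frame(feature = f, statistic = NA_real_,
                        p_value = NA_real_, p_corrected = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    kt <- suppressWarnings(ks.test(a, b))
    pc <- min(1, kt$p.value * length(features))
    data.frame(feature = f, statistic = unname(kt$statistic),
               p_value = kt$p.value, p_corrected = pc,
               significant = pc < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Variance decomposition of firing rates by position and waveform
#'
#' Ordinary least-squares regression (no regularization) of the
#' session-averaged firing rate on the five per-neuron covariates x, y, z
#' position, spike amplitude and peak-to-trough duration, plus an
#' intercept. Predictors are standardized internally for conditioning and
#' the coefficients reported back on the raw scale (numerically equivalent
#' to raw OLS). Reports the unadjusted coefficient of determination.
#'
#' @param table a [feature_table()] (N > 6 complete rows, full-rank
#'   predictors).
#' @param response response column (default `session_mean_rate`).
#' @param features predictor columns.
#' @return an object of class `variance_regression`: `coefficients`
#'   (data.frame with estimate, std. error, t and p per term, raw scale),
#'   `r_squared` (unadjusted), `n`, `fit` (the underlying `lm`).
#' @export
variance_regression <- function(table, response = "session_mean_rate",
                                features = c("x", "y", "z", "amplitude",
                                             "ptt_duration")) {
  cols <- c(response, features)
  df <- table[, cols, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(features) + 1L)
    stop_invalid("need more than %d complete rows", length(features) + 1L)
  mu <- vapply(df[features], mean, numeric(1))
  sg <- vapply(df[features], sd, numeric(1))
  if (any(sg == 0))
    stop_invalid("constant predictor column(s): %s",
                 paste(features[sg == 0], collapse = ", "))
  zs <- as.data.frame(scale(df[features]))
  zs[[response]] <- df[[response]]
  fml <- stats::reformulate(features, response = response)
  fit <- lm(fml, data = zs)
  if (fit$rank < length(features) + 1L) {
    bad <- features[is.na(coef(fit)[features])]
    stop_invalid("collinear predictor column(s): %s",
                 paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  # exact back-transform of the standardized fit to raw predictor units:
  # raw = A %*% standardized, so vcov_raw = A vcov A'
  p <- length(features)
  A <- diag(c(1, 1 / sg))
  A[1L, -1L] <- -mu / sg
  est <- drop(A %*% coef(fit))
  vc <- A %*% stats::vcov(fit) %*% t(A)
  se <- sqrt(diag(vc))
  tv <- est / se
  pv <- 2 * stats::pt(-abs(tv), df = fit$df.residual)
  co <- data.frame(term = c("(Intercept)", features), estimate = est,
                   std_error = se, t_value = tv, p_value = pv,
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = co, r_squared = sm$r.squared,
                 n = nrow(df), fit = fit),
            class = "variance_regression")
}

#' @export
print.variance_regression <- function(x, ...) {
  cat(sprintf("Firing-rate variance regression (n = %d): unadjusted R^2 = %.4f\n",
              x$n, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}
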