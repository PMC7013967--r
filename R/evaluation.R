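#' Tolerance-based classification accuracy
#'
#' A classification counts as accurate when it lies within `tolerance`
#' percentage points of the medical label (inclusive: a 5-point deviation
#' at the default tolerance is still accurate).  The headline accuracy is
#' reported truncated to one decimal place, matching the convention under
#' which 131 accurate out of 156 is reported as 83.9 %.
#'
#' @param predictions numeric improvement predictions (%); `NA` marks an
#'   unclassifiable window and is excluded from the counts.
#' @param labels medical labels (%), same length.
#' @param tolerance percentage points (default 5).
#' @return An `"evaluation_report"`: `n_total`, `n_accurate`, `accuracy`
#'   (exact %), `accuracy_printed` (truncated to one decimal), `tolerance`,
#'   `per_class` (data.frame `label, n, n_accurate, mean_abs_error`),
#'   `n_excluded`.
#' @examples
#' accuracy_within_tolerance(c(42, 46), c(40, 40))$n_accurate  # 1
#' @export
accuracy_within_tolerance <- function(predictions, labels, tolerance = 5) {
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have equal length")
  }
  keep <- !is.na(predictions) & !is.na(labels)
  p <- predictions[keep]
  l <- labels[keep]
  acc <- abs(p - l) <= tolerance
  n_total <- length(p)
  n_accurate <- sum(acc)
  accuracy <- if (n_total) 100 * n_accurate / n_total else NA_real_
  per_class <- if (n_total) {
    agg <- stats::aggregate(
      data.frame(n = rep(1L, n_total), n_accurate = as.integer(acc),
                 abs_error = abs(p - l)),
      by = list(label = l), FUN = sum
    )
    data.frame(label = agg$label, n = agg$n, n_accurate = agg$n_accurate,
               mean_abs_error = agg$abs_error / agg$n)
  } else {
    data.frame(label = numeric(0), n = integer(0), n_accurate = integer(0),
               mean_abs_error = numeric(0))
  }
  structure(
    list(n_total = n_total, n_accurate = n_accurate, accuracy = accuracy,
         accuracy_printed = if (is.na(accuracy)) NA_real_ else
           floor(accuracy * 10) / 10,
         tolerance = tolerance, per_class = per_class,
         n_excluded = sum(!keep)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d/%d within +/- %g points: accuracy %.1f%%\n",
    x$n_accurate, x$n_total, x$tolerance, x$accuracy_printed
  ))
  if (x$n_excluded) cat(sprintf("  (%d invalid window(s) excluded)\n",
                                x$n_excluded))
  invisible(x)
}

#' Jarque-Bera normality test
#'
#' Moment-based test of normality: `JB = n/6 * (S^2 + (K - 3)^2 / 4)`
#' with skewness `S` and (non-excess) kurtosis `K` computed from central
#' sample moments, referred to a chi-square distribution with 2 degrees of
#' freedom.
#'
#' @param x numeric sample (n >= 2, non-degenerate variance).
#' @return List `statistic`, `p_value`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need >= 2 finite values")
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 <= 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                skewness = NA_real_, kurtosis = NA_real_, n = n))
  }
  s <- mean(m^3) / m2^1.5
  k <- mean(m^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = s, kurtosis = k, n = n)
}

#' Rigid vs non-rigid discrimination statistics
#'
#' Reproduces the feature-screening analysis: per feature, group means and
#' standard deviations, a Welch two-tailed t-test p-value, and Jarque-Bera
#' normality verdicts for each group.
#'
#' @param rigid,nonrigid numeric vectors (one feature) or data.frames with
#'   one column per feature.
#' @param alpha significance level for the normality verdict.
#' @return data.frame with one row per feature: `feature`, `mean_rigid`,
#'   `sd_rigid`, `mean_nonrigid`, `sd_nonrigid`, `t_statistic`, `p_value`,
#'   `jb_p_rigid`, `jb_p_nonrigid`, `normal` (both groups pass), and
#'   `degenerate` (zero-variance group, p undefined).
#' @export
discrimination_stats <- function(rigid, nonrigid, alpha = 0.05) {
  if (is.data.frame(rigid) != is.data.frame(nonrigid)) {
    stop("`rigid` and `nonrigid` must both be vectors or both data.frames")
  }
  if (!is.data.frame(rigid)) {
    rigid <- data.frame(feature = rigid)
    nonrigid <- data.frame(feature = nonrigid)
  }
  if (!identical(names(rigid), names(nonrigid))) {
    stop("feature columns must match between groups")
  }
  one <- function(name) {
    a <- rigid[[name]][is.finite(rigid[[name]])]
    b <- nonrigid[[name]][is.finite(nonrigid[[name]])]
    if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
    degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
    if (degenerate) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      jba <- list(p_value = NA_real_)
      jbb <- list(p_value = NA_real_)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      jba <- jarque_bera(a)
      jbb <- jarque_bera(b)
    }
    data.frame(
      feature = name,
      mean_rigid = mean(a), sd_rigid = stats::sd(a),
      mean_nonrigid = mean(b), sd_nonrigid = stats::sd(b),
      t_statistic = unname(tt$statistic), p_value = tt$p.value,
      jb_p_rigid = jba$p_value, jb_p_nonrigid = jbb$p_value,
      normal = if (degenerate) NA else
        jba$p_value > alpha && jbb$p_value > alpha,
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(names(rigid), one))
}
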