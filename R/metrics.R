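#' Relative bias of an activity estimate
#'
#' The relative absolute difference |A - Ak| / A between the true activity A
#' and an estimate Ak. Vectorized over `estimate`.
#'
#' @param true_activity True activity A (nonzero).
#' @param estimate Estimated activity (or vector of estimates).
#' @return Nonnegative fraction(s); multiply by 100 for percent.
#' @examples
#' relative_bias(10, 40)  # 3, i.e. 300%
#' @export
relative_bias <- function(true_activity, estimate) {
  if (true_activity == 0) {
    stop("relative bias is undefined for true activity 0", call. = FALSE)
  }
  abs(true_activity - estimate) / true_activity
}

#' Zamar criterion for slope recovery
#'
#' A rotation-invariant discrepancy between estimated slopes Ak and the true
#' slope A:
#' \deqn{(1/M) \sum_k [ 1 - |1 + A_k A| / (\sqrt{1+A_k^2} \sqrt{1+A^2}) ]}
#' Each summand is 1 minus the cosine of the angle between the directions
#' (1, Ak) and (1, A), so it lies in `[0, 1]`: 0 for perfect recovery of the
#' true line, 1 when the estimated line is perpendicular (Ak = -1/A). Unlike
#' activity-based measures it does not blow up at steep true slopes, making it
#' suitable for comparing methods across activity levels.
#'
#' @param true_activity True activity A.
#' @param estimates Vector of estimated activities Ak over simulation repeats.
#' @return Value in `[0, 1]`.
#' @examples
#' zamar_criterion(10, rep(10, 300))   # 0
#' zamar_criterion(10, -1 / 10)        # 1
#' @export
zamar_criterion <- function(true_activity, estimates) {
  stopifnot(length(estimates) >= 1L)
  a <- true_activity
  terms <- 1 - abs(1 + estimates * a) /
    (sqrt(1 + estimates^2) * sqrt(1 + a^2))
  mean(terms)
}

#' Relative median absolute deviation of activity estimates
#'
#' median(|Ak - median(Ak)|) / A — the raw MAD of the estimates (no normal
#' consistency constant) divided by the true activity. A scale-free measure
#' of estimator precision across simulation repeats.
#'
#' @param true_activity True activity A (nonzero).
#' @param estimates Vector of estimated activities.
#' @return Nonnegative fraction.
#' @examples
#' relative_mad(10, c(9, 10, 11))  # 0.1
#' @export
relative_mad <- function(true_activity, estimates) {
  stopifnot(length(estimates) >= 1L)
  if (true_activity == 0) {
    stop("relative MAD is undefined for true activity 0", call. = FALSE)
  }
  stats::median(abs(estimates - stats::median(estimates))) / true_activity
}

#' Percentile with linear interpolation
#'
#' The p-th percentile of a vector, linearly interpolating between the closest
#' order statistics (the default quantile definition of most statistical
#' environments).
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return A single number.
#' @examples
#' percentile(c(0, 10), 90)  # 9
#' @export
percentile <- function(values, p) {
  stopifnot(length(values) >= 1L, p >= 0, p <= 100)
  unname(stats::quantile(values, probs = p / 100, names = FALSE, type = 7))
}

#' Summarize estimates from repeated simulations
#'
#' Bundles the three evaluation measures for one estimator over M simulation
#' repeats: the Zamar criterion, the 90th percentile of relative bias, and the
#' relative MAD.
#'
#' @param method Estimator label.
#' @param true_activity True activity A.
#' @param estimates Vector of M estimated activities.
#' @return A list of class `evaluation_summary`.
#' @export
evaluation_summary <- function(method, true_activity, estimates) {
  structure(
    list(method = method, m = length(estimates), estimates = estimates,
         true_activity = true_activity,
         zamar = zamar_criterion(true_activity, estimates),
         p90_relative_bias = percentile(relative_bias(true_activity, estimates), 90),
         relative_mad = relative_mad(true_activity, estimates)),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %s, M = %d repeats, true A = %g\n",
              x$method, x$m, x$true_activity))
  cat(sprintf("  Zamar criterion:   %.4g\n", x$zamar))
  cat(sprintf("  P90 relative bias: %.4g (%.3g%%)\n",
              x$p90_relative_bias, 100 * x$p90_relative_bias))
  cat(sprintf("  relative MAD:      %.4g\n", x$relative_mad))
  invisible(x)
}
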