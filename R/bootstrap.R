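#' Bootstrap resampling specification
#'
#' @param n_boot Number of bootstrap resamples (default 999).
#' @param alpha Significance threshold; `0.05` yields a 95% interval.
#' @param method `"basic"` for the basic bootstrap interval
#'   `(2*Ahat - q_{1-alpha/2}, 2*Ahat - q_{alpha/2})`, or `"basic_positive"`
#'   which additionally clamps the lower bound at 0 (activities are
#'   physically nonnegative).
#' @param seed Optional integer seed; when given, repeated calls are
#'   bit-identical.
#' @return A list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_boot = 999L, alpha = 0.05,
                           method = c("basic", "basic_positive"),
                           seed = NULL) {
  stopifnot(n_boot >= 1, alpha > 0, alpha < 1)
  method <- match.arg(method)
  structure(
    list(n_boot = as.integer(n_boot), alpha = alpha, method = method,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "bootstrap_spec"
  )
}

#' Basic bootstrap confidence interval for an activity estimate
#'
#' Resamples replicate pairs (R_i, F_i) with replacement `n_boot` times,
#' re-estimates the slope on each resample, and forms the basic bootstrap
#' interval from the empirical quantiles (linear interpolation between order
#' statistics) of the resampled slopes. Resamples on which the estimator
#' fails — e.g. a ratio resample containing a zero Renilla reading — are
#' dropped and counted; if fewer than half succeed the interval is deemed
#' unreliable and an error is raised.
#'
#' The basic interval does not guarantee that the point estimate lies inside
#' it; only `ci_lower <= ci_upper` is guaranteed.
#'
#' @param data A [replicate_set()] with at least 2 replicates.
#' @param estimator One of `"ratio"`, `"ols"`, `"eiv"`, `"reiv"`, or a
#'   function mapping a `replicate_set` to an `activity_estimate`.
#' @param spec A [bootstrap_spec()].
#' @return A list with `ci_lower`, `ci_upper`, `estimate` (the full-data
#'   `activity_estimate`), `n_failed` (failed resamples), and `n_boot`.
#' @examples
#' set.seed(7)
#' r <- runif(10, 1, 20)
#' rs <- replicate_set(r, 10 * r + rnorm(10, sd = 2))
#' bootstrap_ci(rs, "eiv", bootstrap_spec(n_boot = 199, seed = 1))
#' @export
bootstrap_ci <- function(data, estimator, spec = bootstrap_spec()) {
  data <- as_replicate_set(data)
  if (data$n < 2L) {
    stop("bootstrapping requires at least 2 replicates", call. = FALSE)
  }
  est_fun <- if (is.function(estimator)) estimator else get_estimator(estimator)
  point <- est_fun(data)  # must succeed on the full data

  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec$seed)
  }

  slopes <- rep(NA_real_, spec$n_boot)
  for (b in seq_len(spec$n_boot)) {
    idx <- sample.int(data$n, data$n, replace = TRUE)
    rs <- structure(
      list(renilla = data$renilla[idx], firefly = data$firefly[idx],
           n = data$n),
      class = "replicate_set"
    )
    slopes[b] <- tryCatch(est_fun(rs)$activity, error = function(e) NA_real_)
  }
  ok <- slopes[!is.na(slopes)]
  n_failed <- spec$n_boot - length(ok)
  if (length(ok) < spec$n_boot / 2) {
    stop(sprintf("bootstrap interval unreliable: %d of %d resamples failed",
                 n_failed, spec$n_boot), call. = FALSE)
  }

  q <- stats::quantile(ok, c(spec$alpha / 2, 1 - spec$alpha / 2),
                       names = FALSE, type = 7)
  lower <- 2 * point$activity - q[2]
  upper <- 2 * point$activity - q[1]
  if (spec$method == "basic_positive") {
    lower <- max(lower, 0)
    upper <- max(upper, lower)
  }
  point$ci_lower <- lower
  point$ci_upper <- upper
  list(ci_lower = lower, ci_upper = upper, estimate = point,
       n_failed = n_failed, n_boot = spec$n_boot)
}
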