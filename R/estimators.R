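#' @title Activity estimators for dual-reporter data
#'
#' @description
#' Four estimators of the relative activity A of an experimental reporter,
#' defined as the slope of the proportionality F = A * R between firefly (F)
#' and Renilla (R) luminescence:
#'
#' * [ratio_estimate()] — the prevalent "ratiometric" method, the average of
#'   per-replicate ratios F_i / R_i. Simple but statistically unsound: it
#'   weights low- and high-luminescence replicates equally, and low-signal
#'   replicates produce wildly unreliable ratios.
#' * [ols_estimate()] — through-origin ordinary least squares, minimizing
#'   vertical squared error. Upweights bright replicates, but assumes Renilla
#'   is measured without error.
#' * [eiv_estimate()] — errors-in-variables (orthogonal / total least squares)
#'   regression through the origin, minimizing perpendicular distance and so
#'   acknowledging noise in both reporters.
#' * [reiv_estimate()] — robust errors-in-variables regression: orthogonal
#'   residuals passed through Tukey's bounded loss with an M-estimated scale,
#'   limiting the influence of outliers.
#'
#' All regression estimators fit lines through the origin (no intercept),
#' matching the proportional model: a sample with zero transfection produces
#' no luminescence from either reporter.
#'
#' @name estimators
NULL

new_activity_estimate <- function(activity, method, scale = NA_real_,
                                  ci_lower = NA_real_, ci_upper = NA_real_,
                                  converged = TRUE, degenerate = FALSE) {
  structure(
    list(activity = activity, scale = scale,
         ci_lower = ci_lower, ci_upper = ci_upper,
         method = method, converged = converged, degenerate = degenerate),
    class = "activity_estimate"
  )
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("<activity_estimate> method = %s\n", x$method))
  cat(sprintf("  activity (slope): %.6g\n", x$activity))
  if (!is.na(x$scale)) cat(sprintf("  robust scale:     %.6g RLU\n", x$scale))
  if (!is.na(x$ci_lower) || !is.na(x$ci_upper)) {
    cat(sprintf("  CI:               [%.6g, %.6g]\n", x$ci_lower, x$ci_upper))
  }
  if (!isTRUE(x$converged)) cat("  (did not converge)\n")
  if (isTRUE(x$degenerate)) cat("  (degenerate fit: zero residual scale)\n")
  invisible(x)
}

#' Ratiometric activity estimate
#'
#' Averages the per-replicate firefly/Renilla ratios: A = (1/N) sum(F_i/R_i).
#' All replicates enter unfiltered; negative or near-zero Renilla readings
#' produce the wild ratios that make this estimator unreliable at low
#' transfection efficiency.
#'
#' @param data A [replicate_set()].
#' @return An `activity_estimate`.
#' @examples
#' ratio_estimate(replicate_set(c(1, 2), c(3, 8)))  # 3.5
#' @export
ratio_estimate <- function(data) {
  data <- as_replicate_set(data)
  zero <- which(data$renilla == 0)
  if (length(zero) > 0L) {
    stop(sprintf("Renilla luminescence is exactly zero in replicate(s) %s; the ratio F/R is undefined",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  new_activity_estimate(mean(data$firefly / data$renilla), method = "ratio")
}

#' Through-origin ordinary least-squares activity estimate
#'
#' Slope of F = A * R minimizing the vertical squared error:
#' A = sum(F_i R_i) / sum(R_i^2).
#'
#' @param data A [replicate_set()].
#' @return An `activity_estimate`.
#' @examples
#' ols_estimate(replicate_set(c(1, 2), c(1, 5)))  # 11/5
#' @export
ols_estimate <- function(data) {
  data <- as_replicate_set(data)
  sxx <- sum(data$renilla^2)
  if (sxx == 0) {
    stop("all Renilla values are zero; the through-origin slope is undefined",
         call. = FALSE)
  }
  new_activity_estimate(sum(data$firefly * data$renilla) / sxx, method = "ols")
}

# orthogonal (perpendicular) sum of squared distances of (R_i, F_i) from F = A*R
eiv_objective <- function(a, renilla, firefly) {
  sum((firefly - a * renilla)^2) / (1 + a^2)
}

#' Errors-in-variables (orthogonal regression) activity estimate
#'
#' Minimizes the summed squared perpendicular distance of the points
#' (R_i, F_i) from the line F = A * R, acknowledging measurement error in both
#' reporters. The minimizer solves the quadratic
#' `Sxy A^2 + (Sxx - Syy) A - Sxy = 0` with Sxx = sum(R^2), Syy = sum(F^2),
#' Sxy = sum(R F); of its two roots (which are mutually perpendicular
#' directions) the one with the smaller objective value is returned.
#'
#' @param data A [replicate_set()].
#' @return An `activity_estimate`.
#' @examples
#' eiv_estimate(replicate_set(c(1, 1), c(0, 2)))  # (1 + sqrt(5))/2
#' @export
eiv_estimate <- function(data) {
  data <- as_replicate_set(data)
  r <- data$renilla; f <- data$firefly
  sxx <- sum(r^2); syy <- sum(f^2); sxy <- sum(r * f)
  if (sxy == 0) {
    if (sxx == syy) {
      stop("orientation undefined: the orthogonal objective is constant in the slope",
           call. = FALSE)
    }
    if (syy > sxx) {
      # objective (Syy + A^2 Sxx)/(1 + A^2) decreases toward |A| -> Inf
      stop("orientation undefined: the orthogonal fit is a vertical line (infinite slope)",
           call. = FALSE)
    }
    return(new_activity_estimate(0, method = "eiv"))
  }
  disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  roots <- c((syy - sxx + disc), (syy - sxx - disc)) / (2 * sxy)
  obj <- vapply(roots, eiv_objective, numeric(1), renilla = r, firefly = f)
  if (obj[1] == obj[2]) {
    stop("orientation undefined: both orthogonal directions fit equally well",
         call. = FALSE)
  }
  new_activity_estimate(roots[which.min(obj)], method = "eiv")
}

#' Robust errors-in-variables activity estimate
#'
#' Estimates the slope A of F = A * R by minimizing
#' `sum(rho(r_i(A) / S))`, where `r_i(A) = (F_i - A R_i) / sqrt(1 + A^2)` is
#' the orthogonal residual of point i, `rho` is Tukey's bounded loss with
#' constant `c_rho`, and the scale S is the M-estimate solving
#' `mean(chi(r_i / S)) = kappa` with chi Tukey's loss at `c_chi` (see
#' [estimate_scale()]). The bounded loss caps the influence of gross outliers
#' on the slope.
#'
#' The two coupled problems are solved in the classic two-stage (MM) order,
#' which keeps the high breakdown of the chi-scale and the high efficiency of
#' the rho-loss:
#' \enumerate{
#'   \item \emph{Scale stage:} the profiled scale S(A) — the root of the scale
#'     equation at the orthogonal residuals of slope A — is minimized over A.
#'     Because S(A) can have multiple local minima when outliers mimic an
#'     alternative line, the line's direction angle `atan(A)` is first scanned
#'     on a fixed grid over (-pi/2, pi/2) and the best bracket is then refined
#'     with a local minimizer at tolerance `params$xtol_rel`.
#'   \item \emph{Slope stage:} with the scale frozen at its minimized value,
#'     the Tukey loss at `c_rho` is minimized over A, starting from (and never
#'     accepted if worse than) the scale-stage slope.
#' }
#'
#' If the scale equation has no root — exactly collinear data, where the
#' orthogonal residuals at the EIV slope are all zero — the EIV slope is
#' returned with scale 0 and the `degenerate` flag set: noiseless data are a
#' fixed point, not an error. A near-zero minimized scale (the robust fit
#' passes exactly through all non-outlying points) is likewise reported as
#' degenerate, with the scale-stage slope.
#'
#' @param data A [replicate_set()] with at least 2 replicates.
#' @param params A [robust_params()] object.
#' @return An `activity_estimate` with `activity`, robust `scale` (RLU), and
#'   `converged`/`degenerate` flags.
#' @examples
#' set.seed(1)
#' r <- runif(10, 1, 20)
#' rs <- replicate_set(r, 3 * r + rnorm(10, sd = 0.5))
#' reiv_estimate(rs)
#' @export
reiv_estimate <- function(data, params = robust_params()) {
  data <- as_replicate_set(data)
  if (data$n < 2L) {
    stop("robust errors-in-variables regression requires at least 2 replicates",
         call. = FALSE)
  }
  if (!inherits(params, "robust_params")) {
    stop("'params' must be created with robust_params()", call. = FALSE)
  }
  r <- data$renilla; f <- data$firefly
  # orthogonal residual of each point from the line with direction angle theta
  # (slope A = tan(theta)); equals (F - A R)/sqrt(1 + A^2)
  orth_resid_theta <- function(theta) f * cos(theta) - r * sin(theta)

  a0 <- tryCatch(eiv_estimate(data)$activity,
                 error = function(e) ols_estimate(data)$activity)
  # slope-space residual formula keeps exactly collinear data at exactly zero
  sc0 <- estimate_scale((f - a0 * r) / sqrt(1 + a0^2), params)
  if (sc0$degenerate) {
    return(new_activity_estimate(a0, method = "reiv", scale = 0,
                                 converged = TRUE, degenerate = TRUE))
  }

  # --- scale stage: global scan + local refinement of S(theta) -------------
  profile_scale <- function(theta) estimate_scale(orth_resid_theta(theta), params)$s
  n_grid <- min(181L, max(9L, params$maxeval %/% 4L))
  grid <- seq(-pi / 2, pi / 2, length.out = n_grid + 2L)
  grid <- sort(unique(c(grid[-c(1L, n_grid + 2L)], atan(a0))))
  s_grid <- vapply(grid, profile_scale, numeric(1))
  j <- which.min(s_grid)
  lo <- if (j > 1L) grid[j - 1L] else -pi / 2 + 1e-9
  hi <- if (j < length(grid)) grid[j + 1L] else pi / 2 - 1e-9
  opt_s <- stats::optimize(profile_scale, interval = c(lo, hi),
                           tol = params$xtol_rel)
  theta_s <- if (opt_s$objective <= s_grid[j]) opt_s$minimum else grid[j]
  a_s <- tan(theta_s)
  s_hat <- min(opt_s$objective, s_grid[j])

  # a scale this far below the data magnitude means the robust line passes
  # exactly through the non-outlying points; the rho-stage would be a needle
  # narrower than the optimizer's tolerance, so stop here
  data_scale <- max(abs(r), abs(f))
  if (s_hat <= 1e-10 * data_scale) {
    return(new_activity_estimate(a_s, method = "reiv", scale = 0,
                                 converged = TRUE, degenerate = TRUE))
  }

  # --- slope stage: efficient M-step at the frozen scale -------------------
  loss <- function(a) sum(tukey_loss((f - a * r) / sqrt(1 + a^2) / s_hat,
                                     params$c_rho))
  span <- 0.5 * max(1, abs(a_s))
  converged <- TRUE
  repeat {
    opt <- stats::optimize(loss, interval = c(a_s - span, a_s + span),
                           tol = params$xtol_rel * max(1, abs(a_s)))
    at_edge <- min(opt$minimum - (a_s - span), (a_s + span) - opt$minimum) <
      2 * params$xtol_rel * max(1, abs(a_s)) + 1e-12
    if (!at_edge) break
    span <- span * 4
    if (span > 100 * max(1, abs(a_s))) {  # loss has flattened; keep a_s
      converged <- FALSE
      break
    }
  }
  a_final <- if (converged && opt$objective <= loss(a_s)) opt$minimum else a_s
  new_activity_estimate(a_final, method = "reiv", scale = s_hat,
                        converged = converged)
}

#' Look up an estimator function by its label
#'
#' @param method One of `"ratio"`, `"ols"`, `"eiv"`, `"reiv"`.
#' @return A function taking a [replicate_set()] and returning an
#'   `activity_estimate`.
#' @export
get_estimator <- function(method) {
  switch(match.arg(method, c("ratio", "ols", "eiv", "reiv")),
    ratio = ratio_estimate,
    ols   = ols_estimate,
    eiv   = eiv_estimate,
    reiv  = reiv_estimate
  )
}
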