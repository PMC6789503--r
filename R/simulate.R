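#' Beta parameters for tabulated mean transfection efficiencies
#'
#' Transfection efficiency t varies sample-to-sample and is modeled as a
#' Beta(alpha, beta) draw with mean tbar = alpha/(alpha + beta). The
#' coefficient of variation of the Beta distribution is inversely related to
#' its mean, so low-efficiency experiments are intrinsically noisier — the
#' regime where normalization methods differ most. This lookup returns the
#' canonical (alpha, beta) pairs used throughout the simulation study.
#'
#' @param tbar Mean transfection efficiency; one of 0.1, 0.25, 0.5, 0.75, 0.9.
#' @return A named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_params_for_mean(0.25)  # alpha 2, beta 6
#' @export
beta_params_for_mean <- function(tbar) {
  table <- list(`0.1`  = c(alpha = 2,  beta = 18),
                `0.25` = c(alpha = 2,  beta = 6),
                `0.5`  = c(alpha = 2,  beta = 2),
                `0.75` = c(alpha = 6,  beta = 2),
                `0.9`  = c(alpha = 18, beta = 2))
  key <- as.character(tbar)
  if (length(tbar) != 1L || is.na(match(key, names(table)))) {
    stop(sprintf("'tbar' must be one of %s", paste(names(table), collapse = ", ")),
         call. = FALSE)
  }
  p <- table[[key]]
  stopifnot(isTRUE(all.equal(p["alpha"] / (p["alpha"] + p["beta"]),
                             c(alpha = tbar))))
  p
}

#' Sample per-replicate transfection efficiencies
#'
#' @param n Number of draws.
#' @param alpha,beta Beta distribution parameters (> 0).
#' @return Numeric vector of n efficiencies, each strictly in (0, 1).
#' @export
sample_transfection <- function(n, alpha, beta) {
  stopifnot(n >= 1, alpha > 0, beta > 0)
  stats::rbeta(n, alpha, beta)
}

#' Draws from a contaminated normal error model
#'
#' Each draw is N(0, sigma1^2) with probability 1 - gamma and N(0, sigma2^2)
#' with probability gamma, the component chosen independently per draw. With
#' sigma2 >> sigma1 this mixture produces occasional gross errors — outliers —
#' at frequency gamma.
#'
#' @param n Number of draws.
#' @param sigma1 Standard deviation of the main error component (RLU).
#' @param sigma2 Standard deviation of the contaminating component (RLU).
#' @param gamma Contamination fraction in `[0, 1]` (default 0.05).
#' @return Numeric vector of n errors, with a logical attribute
#'   `"contaminated"` recording which draws came from the contaminating
#'   component.
#' @examples
#' e <- contaminated_normal(1000, sigma1 = 3, sigma2 = 30, gamma = 0.05)
#' mean(attr(e, "contaminated"))  # ~0.05
#' @export
contaminated_normal <- function(n, sigma1, sigma2, gamma = 0.05) {
  stopifnot(n >= 1, sigma1 >= 0, sigma2 >= 0, gamma >= 0, gamma <= 1)
  contaminated <- stats::runif(n) < gamma
  draws <- stats::rnorm(n, mean = 0, sd = ifelse(contaminated, sigma2, sigma1))
  attr(draws, "contaminated") <- contaminated
  draws
}

#' Simulation configuration for synthetic dual-reporter experiments
#'
#' Encodes the generative model of a simulated experiment with N replicates:
#' \deqn{t_i ~ Beta(alpha, beta)}
#' \deqn{R_i = r_max * t_i + CN(sigma11^2, sigma12^2, gamma)}
#' \deqn{F_i = A * r_max * t_i + CN(sigma21^2, sigma22^2, gamma)}
#' where CN is the contaminated normal of [contaminated_normal()] and r_max is
#' the maximal Renilla luminescence (the reading of a hypothetical sample with
#' 100% transfection). Renilla and firefly errors are independent of each
#' other and of t_i.
#'
#' When `sigma21`/`sigma22` are omitted they default to the activity-scaled
#' values `A * sigma11` and `A * sigma12` (see
#' [firefly_sigmas_from_activity()]): a brighter construct has
#' proportionally larger absolute firefly error.
#'
#' @param true_activity True relative activity A (> 0 for the default firefly
#'   error scaling).
#' @param n Replicates per experiment.
#' @param alpha,beta Beta transfection parameters; alternatively supply
#'   `tbar` to take the tabulated pair from [beta_params_for_mean()].
#' @param tbar Optional mean transfection efficiency shortcut.
#' @param r_max Maximal Renilla luminescence (RLU); default 20.
#' @param sigma11,sigma12 Renilla main and contaminating error standard
#'   deviations (RLU).
#' @param sigma21,sigma22 Firefly counterparts; default `A * sigma11` and
#'   `A * sigma12`.
#' @param gamma Contamination fraction (default 0.05).
#' @return A list of class `simulation_config`.
#' @examples
#' simulation_config(true_activity = 10, n = 10, tbar = 0.25,
#'                   sigma11 = 3, sigma12 = 3)
#' @export
simulation_config <- function(true_activity, n, alpha = NULL, beta = NULL,
                              tbar = NULL, r_max = 20,
                              sigma11 = 3, sigma12 = sigma11,
                              sigma21 = NULL, sigma22 = NULL,
                              gamma = 0.05) {
  if (!is.null(tbar)) {
    p <- beta_params_for_mean(tbar)
    alpha <- unname(p["alpha"]); beta <- unname(p["beta"])
  }
  if (is.null(alpha) || is.null(beta)) {
    stop("supply either 'tbar' or both 'alpha' and 'beta'", call. = FALSE)
  }
  if (is.null(sigma21) || is.null(sigma22)) {
    s2 <- firefly_sigmas_from_activity(true_activity, sigma11, sigma12)
    if (is.null(sigma21)) sigma21 <- unname(s2["sigma21"])
    if (is.null(sigma22)) sigma22 <- unname(s2["sigma22"])
  }
  stopifnot(n >= 1, alpha > 0, beta > 0, r_max > 0,
            sigma11 >= 0, sigma12 >= 0, sigma21 >= 0, sigma22 >= 0,
            gamma >= 0, gamma <= 1)
  structure(
    list(true_activity = true_activity, n = as.integer(n),
         alpha = alpha, beta = beta, r_max = r_max,
         sigma11 = sigma11, sigma12 = sigma12,
         sigma21 = sigma21, sigma22 = sigma22, gamma = gamma),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  true activity A = %g, N = %d replicates\n", x$true_activity, x$n))
  cat(sprintf("  transfection: Beta(%g, %g), mean %.3g\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  cat(sprintf("  r_max = %g RLU\n", x$r_max))
  cat(sprintf("  Renilla errors: CN(%g^2, %g^2, %g)\n", x$sigma11, x$sigma12, x$gamma))
  cat(sprintf("  firefly errors: CN(%g^2, %g^2, %g)\n", x$sigma21, x$sigma22, x$gamma))
  invisible(x)
}

#' Activity-scaled firefly error standard deviations
#'
#' Firefly luminescence of a construct with activity A is A-fold brighter than
#' Renilla, and its absolute error standard deviations are assumed to scale
#' accordingly: sigma21 = A * sigma11, sigma22 = A * sigma12.
#'
#' @param a True activity (> 0).
#' @param sigma11,sigma12 Renilla error standard deviations (RLU).
#' @return Named numeric vector `c(sigma21 = , sigma22 = )`.
#' @examples
#' firefly_sigmas_from_activity(10, 3, 3)  # 30, 30
#' @export
firefly_sigmas_from_activity <- function(a, sigma11, sigma12) {
  stopifnot(a > 0, sigma11 >= 0, sigma12 >= 0)
  c(sigma21 = a * sigma11, sigma22 = a * sigma12)
}

#' Simulate one dual-reporter experiment
#'
#' Draws transfection efficiencies and reporter luminescences under `config`.
#' Uses R's current RNG stream; call `set.seed()` beforehand (or use the
#' `seed` argument) for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed set before drawing.
#' @return A [replicate_set()] with attributes `"truth"` (the config) and
#'   `"transfection"` (the drawn t_i).
#' @examples
#' cfg <- simulation_config(true_activity = 10, n = 10, tbar = 0.25,
#'                          sigma11 = 3)
#' simulate_experiment(cfg, seed = 42)
#' @export
simulate_experiment <- function(config, seed = NULL) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must be created with simulation_config()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t_i <- sample_transfection(config$n, config$alpha, config$beta)
  r <- config$r_max * t_i +
    contaminated_normal(config$n, config$sigma11, config$sigma12, config$gamma)
  f <- config$true_activity * config$r_max * t_i +
    contaminated_normal(config$n, config$sigma21, config$sigma22, config$gamma)
  out <- replicate_set(renilla = as.numeric(r), firefly = as.numeric(f))
  attr(out, "truth") <- config
  attr(out, "transfection") <- t_i
  out
}
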