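#' Tukey's biweight loss function
#'
#' The bounded loss rho(t) = t^2/6 * (3 - 3 t^2/c^2 + t^4/c^4) for |t| <= c,
#' clamped to the constant c^2/6 for |t| > c. Boundedness is what caps the
#' influence of any single outlying point on a robust fit: once a residual
#' passes the tuning constant its contribution to the objective stops growing.
#'
#' @param t Numeric vector of (dimensionless) standardized residuals.
#' @param c Tuning constant, > 0. `4.7` gives high efficiency for the slope
#'   loss; `1.56` is the conventional choice for the scale equation.
#' @return Numeric vector of losses, each in `[0, c^2/6]`.
#' @examples
#' tukey_loss(0, 4.7)        # 0
#' tukey_loss(100, 1.56)     # clamped: 1.56^2 / 6
#' @export
tukey_loss <- function(t, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("'c' must be a single positive number", call. = FALSE)
  }
  u <- t / c
  inside <- abs(u) <= 1
  out <- rep.int(c^2 / 6, length(t))
  ti <- t[inside]
  out[inside] <- ti^2 / 6 * (3 - 3 * ti^2 / c^2 + ti^4 / c^4)
  out
}

#' Tuning parameters for the robust errors-in-variables fit
#'
#' @param c_rho Tukey tuning constant for the slope loss (default 4.7).
#' @param c_chi Tukey tuning constant for the scale equation (default 1.56).
#' @param kappa Right-hand side of the scale equation (default 0.05). Must
#'   satisfy 0 < kappa < c_chi^2/6, otherwise the equation can have no root
#'   for any data.
#' @param xtol_rel Relative convergence tolerance for the slope iteration
#'   (default 1e-7).
#' @param maxeval Maximum number of slope-minimization sweeps (default 1000).
#' @return A list of class `robust_params`.
#' @export
robust_params <- function(c_rho = 4.7, c_chi = 1.56, kappa = 0.05,
                          xtol_rel = 1e-7, maxeval = 1000L) {
  stopifnot(c_rho > 0, c_chi > 0, xtol_rel > 0, maxeval >= 1)
  if (!(kappa > 0 && kappa < c_chi^2 / 6)) {
    stop(sprintf("'kappa' must lie in (0, c_chi^2/6) = (0, %g)", c_chi^2 / 6),
         call. = FALSE)
  }
  structure(
    list(c_rho = c_rho, c_chi = c_chi, kappa = kappa,
         xtol_rel = xtol_rel, maxeval = as.integer(maxeval)),
    class = "robust_params"
  )
}

#' M-estimate of residual scale
#'
#' Solves the scale equation mean(chi(r_i / S)) = kappa for S, where chi is
#' Tukey's loss with constant `c_chi`. The left-hand side is non-increasing in
#' S, tends to (fraction of nonzero residuals) * c_chi^2/6 as S -> 0+ and to 0
#' as S -> Inf, so a root exists iff that limiting value exceeds kappa. When it
#' does not (e.g. all residuals are exactly zero: a noiseless, perfectly
#' collinear fit) the scale is reported as 0 with a degenerate flag.
#'
#' @param residuals Numeric vector of residuals (RLU).
#' @param params A [robust_params()] object.
#' @return A list with `s` (the scale, >= 0, RLU) and `degenerate` (TRUE when
#'   no root exists and `s` is 0 by convention).
#' @examples
#' estimate_scale(c(-1, 0, 1))$s
#' estimate_scale(rep(0, 5))          # degenerate, s = 0
#' @export
estimate_scale <- function(residuals, params = robust_params()) {
  stopifnot(is.numeric(residuals), length(residuals) >= 1L, all(is.finite(residuals)))
  c_chi <- params$c_chi
  kappa <- params$kappa
  lhs <- function(s) mean(tukey_loss(residuals / s, c_chi)) - kappa

  # limit of the LHS as S -> 0+: nonzero residuals each contribute c_chi^2/6
  lim0 <- mean(residuals != 0) * c_chi^2 / 6
  if (lim0 <= kappa) {
    return(list(s = 0, degenerate = TRUE))
  }

  rmax <- max(abs(residuals))
  # bracket the root: expand upward until the LHS drops below kappa,
  # downward until it exceeds kappa (monotone, so doubling/halving terminates)
  hi <- rmax
  while (lhs(hi) > 0) hi <- hi * 2
  lo <- rmax * 1e-8
  while (lhs(lo) < 0) lo <- lo / 2
  root <- stats::uniroot(lhs, lower = lo, upper = hi, tol = 1e-10 * hi)
  list(s = root$root, degenerate = FALSE)
}
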