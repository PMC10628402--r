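#' Log-risk slope from a relative risk per increment
#'
#' Epidemiological studies report relative risks per concentration
#' increment (typically 10 µg/m³). Under the log-linear model
#' RR(x) = exp(beta (x - x0)) the per-unit slope is beta = ln(RR)/increment.
#'
#' @param rr relative risk (> 0) for a `increment` µg/m³ rise.
#' @param increment the concentration increment the RR refers to, µg/m³.
#' @return the slope beta per µg/m³ (vectorized over `rr`).
#' @export
#' @examples
#' beta_from_rr(1.062, 10) # 0.006015392...
beta_from_rr <- function(rr, increment = 10) {
  if (!is.numeric(rr) || any(rr <= 0))
    stop("relative risk must be > 0")
  if (!is.numeric(increment) || length(increment) != 1 || increment <= 0)
    stop("increment must be > 0")
  log(rr) / increment
}

#' Log-linear concentration-response function
#'
#' The standard burden-of-disease CRF RR(x) = exp(beta (x - x0)) for
#' x > x0 and exactly 1 below the counterfactual x0 (excess risk is never
#' attributed below the guideline level). The slope triple
#' (central, low, high) is derived from the source RR and its 95% CI, so CI
#' propagation amounts to evaluating the curve at the bound slopes.
#'
#' @param rr relative risk per `increment` µg/m³: either a single value or
#'   a length-3 vector `c(central, low, high)` carrying the 95% CI.
#' @param increment concentration increment of the source RR, µg/m³
#'   (default 10).
#' @param counterfactual default counterfactual concentration x0, µg/m³.
#' @return an object of class `c("loglinear_crf", "crf")` with fields
#'   `beta` (an ordered triple), `source_rr`, `increment`,
#'   `counterfactual`.
#' @export
#' @examples
#' crf <- loglinear_crf(c(1.062, 1.040, 1.083), counterfactual = 10)
#' relative_risk(crf, 35.45)
loglinear_crf <- function(rr, increment = 10, counterfactual = 10) {
  if (length(rr) == 1) rr <- rep(rr, 3)
  stopifnot(length(rr) == 3, is.numeric(rr))
  if (counterfactual < 0) stop("counterfactual must be >= 0")
  src <- triple(rr[[1]], rr[[2]], rr[[3]])
  beta <- triple(beta_from_rr(rr[[1]], increment),
                 beta_from_rr(rr[[2]], increment),
                 beta_from_rr(rr[[3]], increment))
  structure(list(beta = beta, source_rr = src, increment = increment,
                 counterfactual = counterfactual),
            class = c("loglinear_crf", "crf"))
}

#' @export
print.loglinear_crf <- function(x, ...) {
  cat("Log-linear CRF: RR ", fmt_hu(x$source_rr[["central"]], 4), " (",
      fmt_hu(x$source_rr[["low"]], 4), "-",
      fmt_hu(x$source_rr[["high"]], 4), ") per ", x$increment,
      " µg/m³, counterfactual ", x$counterfactual, " µg/m³\n", sep = "")
  invisible(x)
}

#' Integrated exposure-response (IER) curve
#'
#' The saturating Burnett-family curve used for cause-specific endpoints
#' (lung cancer, ALRI, COPD, IHD, stroke):
#' RR(z) = 1 + alpha (1 - exp(-gamma (z - zcf)^delta)) for z > zcf, and 1
#' at or below the counterfactual zcf. It pools ambient air pollution,
#' household solid-fuel and smoking evidence, rises monotonically above
#' zcf and saturates at 1 + alpha.
#'
#' @param cause one of `"LC"`, `"ALRI"`, `"COPD"`, `"IHD"`, `"stroke"`.
#' @param alpha saturation excess risk (>= 0).
#' @param gamma rate parameter (>= 0).
#' @param delta shape exponent (> 0).
#' @param zcf counterfactual concentration, µg/m³ (>= 0).
#' @return an object of class `c("ier_crf", "crf")`.
#' @export
ier_crf <- function(cause = c("LC", "ALRI", "COPD", "IHD", "stroke"),
                    alpha, gamma, delta = 1, zcf = 2.4) {
  cause <- match.arg(cause)
  stopifnot(is.numeric(alpha), is.numeric(gamma), is.numeric(delta),
            is.numeric(zcf))
  if (alpha < 0) stop("alpha must be >= 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  if (zcf < 0) stop("zcf must be >= 0")
  structure(list(cause = cause, alpha = alpha, gamma = gamma,
                 delta = delta, zcf = zcf),
            class = c("ier_crf", "crf"))
}

#' @export
print.ier_crf <- function(x, ...) {
  cat("IER curve (", x$cause, "): alpha = ", signif(x$alpha, 6),
      ", gamma = ", x$gamma, ", delta = ", x$delta,
      ", counterfactual ", x$zcf, " µg/m³\n", sep = "")
  invisible(x)
}

#' Relative risk at a concentration
#'
#' Evaluate a concentration-response function at exposure `x` relative to
#' its counterfactual. Below the counterfactual the RR is exactly 1: the
#' counterfactual is a hard threshold and negative attribution never
#' occurs.
#'
#' @param object a `"loglinear_crf"` or `"ier_crf"`.
#' @param x concentration, µg/m³ (scalar).
#' @param x0 counterfactual override, µg/m³; defaults to the one stored in
#'   the CRF.
#' @param ... unused.
#' @return a [triple()] of relative risks `(central, low, high)`. For IER
#'   curves, which carry a single parameter set, the three components
#'   coincide.
#' @export
relative_risk <- function(object, x, ...) UseMethod("relative_risk")

#' @rdname relative_risk
#' @export
relative_risk.loglinear_crf <- function(object, x, x0 = NULL, ...) {
  if (is.null(x0)) x0 <- object$counterfactual
  stopifnot(is.numeric(x), length(x) == 1, x >= 0, x0 >= 0)
  if (x <= x0) return(triple(1, 1, 1))
  d <- x - x0
  triple(exp(object$beta[["central"]] * d),
         exp(object$beta[["low"]] * d),
         exp(object$beta[["high"]] * d))
}

#' @rdname relative_risk
#' @export
relative_risk.ier_crf <- function(object, x, x0 = NULL, ...) {
  if (is.null(x0)) x0 <- object$zcf
  stopifnot(is.numeric(x), length(x) == 1, x >= 0)
  if (x <= x0) return(triple(1, 1, 1))
  r <- 1 + object$alpha * (1 - exp(-object$gamma * (x - x0)^object$delta))
  triple(r, r, r)
}

#' @export
predict.crf <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  t(vapply(x, function(xi) unclass(relative_risk(object, xi)),
           numeric(3)))
}

#' @export
plot.crf <- function(x, from = 0, to = 60, n = 301, ...) {
  grid <- seq(from, to, length.out = n)
  rr <- predict(x, grid)
  graphics::matplot(grid, rr, type = "l", lty = c(1, 2, 2),
                    col = c("black", "grey40", "grey40"),
                    xlab = expression(paste("concentration (", mu, "g/",
                                            m^3, ")")),
                    ylab = "relative risk", ...)
  x0 <- if (inherits(x, "ier_crf")) x$zcf else x$counterfactual
  graphics::abline(v = x0, col = "grey70", lty = 3)
  invisible(rr)
}

#' Relative risk implied by an attributable proportion
#'
#' Inverts AP = 1 - 1/RR: the RR consistent with a stated attributable
#' proportion. Useful when a published analysis prints AP but not the
#' underlying RR at the study exposure.
#'
#' @param ap attributable proportion, in \[0, 1).
#' @return relative risk 1/(1 - ap) (vectorized).
#' @export
#' @examples
#' rr_from_ap(0.1842) # 1.2258
rr_from_ap <- function(ap) {
  if (!is.numeric(ap) || any(ap < 0) || any(ap >= 1))
    stop("attributable proportion must lie in [0, 1)")
  1 / (1 - ap)
}

#' Calibrate an IER curve's scale to a known (exposure, RR) point
#'
#' Solves for alpha with gamma, delta and zcf held at the template's
#' values, so that the returned curve passes through `(z_obs, rr_obs)`
#' exactly. This lets IER endpoints be represented when the underlying GBD
#' parameter sets are not published but the RR at the study exposure is.
#'
#' @param curve_template an [ier_crf()] providing gamma, delta, zcf (its
#'   alpha is ignored).
#' @param z_obs observed exposure, µg/m³, strictly above the template zcf.
#' @param rr_obs observed relative risk at `z_obs`, > 1.
#' @return an [ier_crf()] with alpha = (rr_obs - 1) /
#'   (1 - exp(-gamma (z_obs - zcf)^delta)).
#' @export
fit_ier_scale <- function(curve_template, z_obs, rr_obs) {
  if (!inherits(curve_template, "ier_crf"))
    stop("curve_template must be an ier_crf")
  if (z_obs <= curve_template$zcf)
    stop("z_obs must exceed the counterfactual zcf")
  if (rr_obs <= 1) stop("rr_obs must be > 1")
  sat <- 1 - exp(-curve_template$gamma *
                   (z_obs - curve_template$zcf)^curve_template$delta)
  if (sat <= 0)
    stop("infeasible calibration: saturation term is zero at z_obs ",
         "(gamma = 0?)")
  ier_crf(curve_template$cause, alpha = (rr_obs - 1) / sat,
          gamma = curve_template$gamma, delta = curve_template$delta,
          zcf = curve_template$zcf)
}
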