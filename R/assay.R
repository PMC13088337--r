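## Assay-derived efficiency metrics and statistics: conversion, total
## turnover number, coupling efficiency, Michaelis-Menten kinetics, Pearson
## correlation with two-sided t significance.

#' Substrate conversion percentage
#'
#' `100 * product / (product + substrate)`, both in the same concentration
#' unit (mM).
#'
#' @param product_mM,substrate_mM Product and residual substrate amounts
#'   (vectorized; each pair must not be both zero).
#' @return Conversion in percent.
#' @examples
#' conversion_percent(8.16, 1.84)  # 81.6
#' @export
conversion_percent <- function(product_mM, substrate_mM) {
  stopifnot(all(product_mM >= 0), all(substrate_mM >= 0))
  tot <- product_mM + substrate_mM
  if (any(tot == 0)) stop("product and substrate cannot both be zero")
  100 * product_mM / tot
}

#' Total turnover number
#'
#' Moles of product per mole of enzyme: `product / enzyme` with the
#' mM-vs-uM unit mismatch handled (x1000).
#'
#' @param product_mM Product concentration, mM.
#' @param enzyme_uM Enzyme concentration, uM (> 0).
#' @return TTN (unitless).
#' @examples
#' ttn(0.6444, 0.2)  # 3222
#' @export
ttn <- function(product_mM, enzyme_uM) {
  stopifnot(all(product_mM >= 0))
  if (any(enzyme_uM <= 0)) stop("enzyme concentration must be > 0")
  1000 * product_mM / enzyme_uM
}

#' Coupling efficiency percentage
#'
#' Fraction of consumed NAD(P)H reducing equivalents ending up in product:
#' `100 * product / nadh_consumed`.
#'
#' @param product_mM Product formed, mM.
#' @param nadh_mM NADH consumed, mM (> 0).
#' @return Coupling efficiency in percent.
#' @export
coupling_percent <- function(product_mM, nadh_mM) {
  stopifnot(all(product_mM >= 0))
  if (any(nadh_mM <= 0)) stop("NADH consumption must be > 0")
  100 * product_mM / nadh_mM
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = Vmax S / (Km + S)`, parameterized on the
#' log scale so `Km` and `Vmax` cannot escape to non-positive values.
#' Initialization: `Vmax0 = max(v)`, `Km0 = median(S)`. No weighting by
#' default; `weighting = "inv_v2"` applies 1/v^2 weights.
#'
#' Velocities may be per-enzyme turnovers (1/s; the default interpretation,
#' matching kcat reporting) or concentration rates (mM/s) together with
#' `enzyme_conc_uM` to normalize, in which case
#' `kcat = Vmax / enzyme_conc` (with the mM-vs-uM factor applied).
#'
#' @param substrate_mM Substrate concentrations, mM (>= 3 distinct, > 0).
#' @param velocity Velocities, same length.
#' @param enzyme_conc_uM Optional enzyme concentration (uM) when `velocity`
#'   is in mM/s.
#' @param weighting `"none"` (default) or `"inv_v2"`.
#' @return An `etk_mmfit`: `Km` (mM), `Vmax`, `kcat` (1/s),
#'   `catalytic_efficiency` (kcat/Km, 1/(mM s)), `residual_sse`, and
#'   `boundary` (`"none"`, `"lower"` or `"upper"`, flagged when the fitted
#'   `Km` runs away below/above the sampled concentration range -- the
#'   saturated and linear degenerate designs).
#' @examples
#' S <- c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 5)
#' v <- 1.47 * S / (0.18 + S)
#' fit_michaelis_menten(S, v)
#' @export
fit_michaelis_menten <- function(substrate_mM, velocity,
                                 enzyme_conc_uM = NULL,
                                 weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  S <- as.numeric(substrate_mM)
  v <- as.numeric(velocity)
  if (length(S) != length(v)) stop("substrate and velocity lengths differ")
  if (length(unique(S)) < 3L) stop("need at least 3 distinct concentrations")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  if (all(v <= 0)) stop("velocities are all non-positive")
  w <- if (weighting == "inv_v2") 1 / pmax(v, max(v) * 1e-6)^2
       else rep(1, length(v))
  start <- list(lV = log(max(v)), lK = log(stats::median(S)))
  sw <- sqrt(w)
  ## optimizer stop reasons are re-examined below via fit$info; its warnings
  ## about hitting iteration caps would be spurious for boundary designs
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) sw * (v - exp(p$lV) * S / (exp(p$lK) + S)),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000,
                                           ftol = 1e-15, ptol = 1e-15)),
    warning = function(w) invokeRestart("muffleWarning"))
  p <- unlist(fit$par)
  Km <- exp(p[["lK"]])
  Vmax <- exp(p[["lV"]])
  boundary <- if (Km < min(S) / 100) "lower"
              else if (Km > max(S) * 100) "upper"
              else "none"
  ## a Km running away below/above the sampled range (saturated or linear
  ## designs) stalls the optimizer in a flat valley: flag, do not fail
  if (!fit$info %in% 1:4 && boundary == "none")
    stop("Michaelis-Menten fit failed to converge: ", fit$message,
         " (info ", fit$info, ", ", fit$niter, " iterations)")
  kcat <- if (is.null(enzyme_conc_uM)) Vmax
          else 1000 * Vmax / enzyme_conc_uM
  structure(list(Km = Km, Vmax = Vmax, kcat = kcat,
                 catalytic_efficiency = kcat / Km,
                 residual_sse = fit$deviance,
                 boundary = boundary, n = length(S)),
            class = "etk_mmfit")
}

#' @export
print.etk_mmfit <- function(x, ...) {
  cat(sprintf(
    "etk_mmfit: Km = %.4g mM, kcat = %.4g /s, kcat/Km = %.4g /(mM s)%s\n",
    x$Km, x$kcat, x$catalytic_efficiency,
    if (x$boundary != "none") paste0(" [Km at ", x$boundary, " bound]")
    else ""))
  invisible(x)
}

#' Pearson correlation with two-sided significance
#'
#' `r = cov(x, y) / (sd(x) sd(y))`; the two-sided p-value comes from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, length n >= 3, both with non-zero variance.
#' @return An `etk_cor`: `r`, `p_two_sided`, `n`, `t`, `df`.
#' @examples
#' pearson_cor(c(25, 786, 1306, 2011), c(2.78, 23.19, 30.13, 38.03))
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate),
                 p_two_sided = ct$p.value,
                 n = length(x),
                 t = unname(ct$statistic),
                 df = unname(ct$parameter)),
            class = "etk_cor")
}

#' @export
print.etk_cor <- function(x, ...) {
  cat(sprintf("etk_cor: r = %.4f, p = %.4g (two-sided, n = %d, df = %d)\n",
              x$r, signif(x$p_two_sided, 4), x$n, x$df))
  invisible(x)
}
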