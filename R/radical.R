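#' Polynomial model of the normalized hydrogen peroxide level
#'
#' During anodic water electrolysis, H2O2 and hydroxyl radicals are linked by
#' a recombination equilibrium, so the measured H2O2 time course carries the
#' radical dose information. The measured normalized level is represented as
#' a polynomial in time, `B0 + B1 t + B2 t^2 + ...`, valid only on the fitted
#' domain; evaluation is clamped at zero (a concentration cannot be negative)
#' and evaluation outside the domain is an error, never silent extrapolation.
#'
#' @param coefficients numeric vector `(B0, B1, ..., Bm)`; `Bq` has units
#'   1/s^q.
#' @param t_max_s upper end of the valid domain `[0, t_max_s]` in seconds.
#' @param fit_r2 optional coefficient of determination of the fit.
#' @return an object of class `h2o2_poly`.
#' @export
h2o2_poly <- function(coefficients, t_max_s, fit_r2 = NA_real_) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || any(!is.finite(coefficients)))
    stop("coefficients must be a finite numeric vector (B0, B1, ...)")
  if (!is.numeric(t_max_s) || length(t_max_s) != 1L || t_max_s <= 0)
    stop("t_max_s must be a single positive number (seconds)")
  structure(list(coefficients = coefficients, t_max_s = t_max_s,
                 fit_r2 = fit_r2),
            class = "h2o2_poly")
}

# raw polynomial value (no clamping); vectorized in t
poly_value <- function(coefficients, t) {
  out <- numeric(length(t))
  for (q in seq_along(coefficients))
    out <- out + coefficients[q] * t^(q - 1L)
  out
}

#' Evaluate the H2O2 polynomial (clamped at zero)
#'
#' @param poly an [h2o2_poly()].
#' @param t time(s) in seconds, inside the valid domain.
#' @return normalized H2O2 level(s), >= 0.
#' @export
h2o2_star <- function(poly, t) {
  stopifnot(inherits(poly, "h2o2_poly"))
  if (any(t < 0) || any(t > poly$t_max_s))
    stop("t outside the polynomial's valid domain [0, ", poly$t_max_s, "] s")
  pmax(poly_value(poly$coefficients, t), 0)
}

#' Fit a polynomial to a measured H2O2 series
#'
#' Ordinary least-squares polynomial fit of the normalized H2O2 level against
#' time. A cubic (the default order) is the shape that describes the typical
#' ramp-then-plateau H2O2 evolution at a constant current density. Time is
#' rescaled internally to `[0, 1]` before solving and the coefficients are
#' transformed back, so the fit is well conditioned up to high orders.
#'
#' @param time_s sampling times in seconds; non-negative, strictly increasing.
#' @param h2o2 measured normalized H2O2 values.
#' @param order polynomial order (default 3).
#' @return an [h2o2_poly()] with `fit_r2` filled in and valid domain
#'   `[0, max(time_s)]`.
#' @export
fit_h2o2_polynomial <- function(time_s, h2o2, order = 3L) {
  time_s <- as.numeric(time_s)
  h2o2 <- as.numeric(h2o2)
  if (length(time_s) != length(h2o2))
    stop("time_s and h2o2 must have the same length")
  if (length(time_s) < order + 2L)
    stop("need at least order + 2 = ", order + 2L, " points")
  if (any(time_s < 0)) stop("times must be non-negative")
  if (any(diff(time_s) <= 0))
    stop("times must be strictly increasing (duplicate or unordered times)")
  t_max <- max(time_s)
  tau <- time_s / t_max
  X <- outer(tau, 0:order, `^`)
  fit <- stats::lm.fit(X, h2o2)
  if (any(is.na(fit$coefficients)))
    stop("rank-deficient polynomial design; reduce the order")
  coef_tau <- fit$coefficients
  coefficients <- coef_tau / t_max^(0:order)
  rss <- sum(fit$residuals^2)
  tss <- sum((h2o2 - mean(h2o2))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  h2o2_poly(coefficients, t_max_s = t_max, fit_r2 = r2)
}

#' Hydroxyl-radical profile derived from H2O2 via the equilibrium
#' proportionality
#'
#' The recombination equilibrium `.OH + .OH <-> H2O2` makes the normalized
#' radical level proportional to the normalized H2O2 level:
#' `OH* = k_prop * H2O2*`. `k_prop` is an electrode-and-current-density
#' characteristic; `reference_conc` converts the normalized level to absolute
#' molarity (`[.OH] = OH* * C0`).
#'
#' @param poly an [h2o2_poly()].
#' @param k_prop proportionality factor (> 0, dimensionless in the normalized
#'   frame).
#' @param reference_conc parent initial concentration C0 in mol/L.
#' @return an object of class `oh_profile`.
#' @export
oh_profile <- function(poly, k_prop, reference_conc) {
  stopifnot(inherits(poly, "h2o2_poly"))
  if (!is.numeric(k_prop) || length(k_prop) != 1L || k_prop <= 0 ||
      !is.finite(k_prop))
    stop("k_prop must be a single positive number")
  if (!is.numeric(reference_conc) || length(reference_conc) != 1L ||
      reference_conc <= 0)
    stop("reference_conc must be a single positive number (mol/L)")
  structure(list(poly = poly, k_prop = k_prop,
                 reference_conc = reference_conc),
            class = "oh_profile")
}

#' Normalized hydroxyl-radical level at time t
#'
#' @param profile an [oh_profile()].
#' @param t time(s) in seconds inside the polynomial domain.
#' @return normalized radical level(s), >= 0.
#' @export
oh_star <- function(profile, t) {
  stopifnot(inherits(profile, "oh_profile"))
  profile$k_prop * h2o2_star(profile$poly, t)
}

# antiderivative of the raw (unclamped) polynomial
poly_antideriv <- function(coefficients, t) {
  out <- numeric(length(t))
  for (q in seq_along(coefficients))
    out <- out + coefficients[q] * t^q / q
  out
}

#' Hydroxyl-radical exposure over a time interval
#'
#' The exposure `u = integral of [.OH] dt` (M s) is the natural variable of
#' the linear chain: [bateman_chain()] evaluated at `u(t)` gives the exact
#' trajectory. The integral of the clamped polynomial is computed in closed
#' form, splitting the interval at real roots of the polynomial so that
#' negative excursions contribute zero.
#'
#' @param profile an [oh_profile()].
#' @param t0,t1 interval bounds in seconds, `t0 <= t1`, both inside the
#'   domain.
#' @return exposure in M s.
#' @export
oh_exposure <- function(profile, t0, t1) {
  stopifnot(inherits(profile, "oh_profile"))
  poly <- profile$poly
  if (length(t0) != 1L || length(t1) != 1L || t0 > t1)
    stop("need scalar bounds with t0 <= t1")
  if (t0 < 0 || t1 > poly$t_max_s)
    stop("interval outside the polynomial's valid domain")
  cf <- poly$coefficients
  # breakpoints where the polynomial may change sign
  brk <- numeric(0)
  if (length(cf) > 1L && any(cf[-1L] != 0)) {
    rts <- polyroot(cf)
    re <- Re(rts)[abs(Im(rts)) < 1e-8 * pmax(abs(Re(rts)), 1)]
    brk <- sort(re[re > t0 & re < t1])
  }
  pts <- unique(c(t0, brk, t1))
  u_norm <- 0
  for (i in seq_len(length(pts) - 1L)) {
    a <- pts[i]; b <- pts[i + 1L]
    if (poly_value(cf, (a + b) / 2) > 0)
      u_norm <- u_norm + poly_antideriv(cf, b) - poly_antideriv(cf, a)
  }
  profile$reference_conc * profile$k_prop * u_norm
}

#' Linear dependence of the radical proportionality factor on current density
#'
#' The effective radical yield of a given electrode scales with the applied
#' current density `j` (mA/cm^2); over the supported range the proportionality
#' factor follows a straight line `k(j) = slope * j + intercept`.
#'
#' @param slope slope in cm^2/mA.
#' @param intercept dimensionless intercept.
#' @param fit_r2 optional R^2 of the calibration fit.
#' @return an object of class `current_density_law`.
#' @export
current_density_law <- function(slope, intercept, fit_r2 = NA_real_) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("slope must be a single finite number (cm^2/mA)")
  if (!is.numeric(intercept) || length(intercept) != 1L ||
      !is.finite(intercept))
    stop("intercept must be a single finite number")
  structure(list(slope = slope, intercept = intercept, fit_r2 = fit_r2),
            class = "current_density_law")
}

#' Proportionality factor at a given current density
#'
#' @param law a [current_density_law()].
#' @param j current density in mA/cm^2, > 0 (j = 0 returns the intercept).
#' @return the proportionality factor `k(j)`.
#' @export
k_of_j <- function(law, j) {
  stopifnot(inherits(law, "current_density_law"))
  if (any(j < 0)) stop("current density must be non-negative")
  k <- law$slope * j + law$intercept
  if (any(k <= 0))
    stop("law yields a non-positive proportionality factor at the requested j")
  k
}

#' Calibrate the current-density law from (j, k) observations
#'
#' Ordinary least-squares line through proportionality factors determined at
#' several current densities.
#'
#' @param j current densities in mA/cm^2 (at least two distinct values).
#' @param k proportionality factors determined at each `j`.
#' @return a [current_density_law()] with `fit_r2` filled in.
#' @export
fit_current_law <- function(j, k) {
  j <- as.numeric(j); k <- as.numeric(k)
  if (length(j) != length(k) || length(j) < 2L)
    stop("need at least two (j, k) pairs")
  if (length(unique(j)) < 2L)
    stop("all current densities identical; the slope is not identifiable")
  fit <- stats::lm(k ~ j)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((k - mean(k))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  current_density_law(slope = unname(stats::coef(fit)[2L]),
                      intercept = unname(stats::coef(fit)[1L]),
                      fit_r2 = r2)
}
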