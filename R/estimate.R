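#' Goodness-of-fit statistics for a predicted series
#'
#' @param predicted model predictions.
#' @param observed observations (same length, >= 2 points).
#' @return list with `r2` (about the observed mean), `rmse` (`sqrt(RSS/n)`)
#'   and `rss`.
#' @export
goodness_stats <- function(predicted, observed) {
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  if (length(predicted) != length(observed) || length(observed) < 2L)
    stop("predicted and observed must have equal length >= 2")
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("observed series has zero variance; R^2 is undefined")
  list(r2 = 1 - rss / tss,
       rmse = sqrt(rss / length(observed)),
       rss = rss)
}

# assemble the common fit-result structure
make_fit_result <- function(estimates, ci95, stats, convergence) {
  structure(list(estimates = estimates, ci95 = ci95, stats = stats,
                 convergence = convergence),
            class = "ohkin_fit")
}

#' @export
print.ohkin_fit <- function(x, ...) {
  cat("Kinetic fit (", if (isTRUE(x$convergence$success)) "converged"
      else "NOT converged", ", ", x$convergence$iterations,
      " iterations, final cost ", format(x$convergence$cost), ")\n", sep = "")
  for (nm in names(x$estimates)) {
    ci <- x$ci95[[nm]]
    cat(sprintf("  %-8s %s", nm, format(x$estimates[[nm]], digits = 4)))
    if (!is.null(ci) && is.finite(ci)) cat(" +/-", format(ci, digits = 3))
    cat("\n")
  }
  if (!is.null(x$stats$overall))
    cat("  overall: R2 =", format(x$stats$overall$r2, digits = 4),
        " RMSE =", format(x$stats$overall$rmse, digits = 4),
        " RSS =", format(x$stats$overall$rss, digits = 4), "\n")
  invisible(x)
}

#' Estimate the radical proportionality factor from the parent decay
#'
#' One-parameter bounded least squares on `log10(k_prop)`: with the chain
#' rate constants held at literature priors, the parent pollutant's simulated
#' normalized profile is matched to its measured profile. The log10
#' parameterization handles the scale of k (~1e-10) gracefully and makes the
#' optimum insensitive to the starting value.
#'
#' @param time_s measurement times in seconds.
#' @param parent_star measured normalized parent concentrations.
#' @param poly the fitted [h2o2_poly()].
#' @param rates fixed absolute per-step constants in 1/(M s) (priors).
#' @param system the [chain_system()].
#' @param lower,upper bounds on `k_prop` (defaults 1e-14 and 1e-6).
#' @param init starting value for `k_prop` (default 1e-9).
#' @param rtol,atol solver tolerances passed to [simulate_chain()].
#' @return an `ohkin_fit` with the estimated `k_prop`, its delta-method 95%
#'   confidence half-width, parent-series fit statistics and convergence
#'   diagnostics.
#' @export
fit_proportionality <- function(time_s, parent_star, poly, rates, system,
                                lower = 1e-14, upper = 1e-6, init = 1e-9,
                                rtol = 1e-8, atol = 1e-10) {
  time_s <- as.numeric(time_s)
  if (length(time_s) < 3L) stop("need at least 3 measurement points")
  parent <- system$species[1L]
  sim_parent <- function(log10k) {
    prof <- oh_profile(poly, 10^log10k, system$c0_mol_L)
    grid <- if (time_s[1L] > 0) c(0, time_s) else time_s
    traj <- simulate_chain(system, rates, prof, grid, rtol = rtol,
                           atol = atol)
    traj$states[match(time_s, traj$times), parent]
  }
  res_fn <- function(p) parent_star - sim_parent(p[1L])
  fit <- minpack.lm::nls.lm(par = log10(init), lower = log10(lower),
                            upper = log10(upper), fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-12))
  success <- fit$info %in% 1:4
  k_hat <- 10^fit$par[1L]
  n <- length(time_s)
  ci <- NA_real_
  se_log <- tryCatch(summary(fit)$coefficients[1L, "Std. Error"],
                     error = function(e) NA_real_)
  if (is.finite(se_log) && n > 1L)
    ci <- k_hat * log(10) * se_log * stats::qt(0.975, df = n - 1L)
  pred <- sim_parent(fit$par[1L])
  st <- goodness_stats(pred, parent_star)
  make_fit_result(
    estimates = list(k_prop = k_hat),
    ci95 = list(k_prop = ci),
    stats = list(parent = st, overall = st),
    convergence = list(iterations = fit$niter, cost = fit$deviance,
                       success = success, message = fit$message))
}

#' Estimate the chain rate constants from measured pool profiles
#'
#' Joint bounded nonlinear least squares over the dimensionless per-step
#' constants, with the radical profile (and hence `k_prop`) held fixed.
#' Residuals are stacked over all measured pools with equal weight. The fit
#' runs in the dimensionless frame of the supplied normalization scheme (the
#' frame in which the constants are O(1)); absolute constants are recovered
#' via [rescale_constants()]. 95% confidence half-widths come from the
#' linearized covariance `s^2 (J'J)^-1` with a Student-t quantile at
#' `n_points - n_params` degrees of freedom.
#'
#' @param data data frame with column `time_s` and one column per measured
#'   pool, named exactly as the chain's species. All series share the
#'   `time_s` base; interpolation is deliberately not performed.
#' @param profile the fixed [oh_profile()].
#' @param system the [chain_system()].
#' @param scheme a [normalization_scheme()] defining the dimensionless frame.
#' @param lower,upper bounds on the dimensionless constants (defaults 0 and
#'   10).
#' @param init starting dimensionless constants (scalar or vector; default
#'   0.5).
#' @param rtol,atol solver tolerances passed to [simulate_chain()].
#' @return an `ohkin_fit`; `estimates` holds the absolute constants (named
#'   `k1, k2, ...` by step) plus `dimensionless`, `stats` holds per-pool and
#'   overall R^2/RMSE/RSS.
#' @export
fit_rate_constants <- function(data, profile, system, scheme,
                               lower = 0, upper = 10, init = 0.5,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "chain_system"),
            inherits(scheme, "normalization_scheme"))
  if (!"time_s" %in% names(data)) stop("data must contain a time_s column")
  pools <- intersect(system$species, names(data))
  if (length(pools) < 1L)
    stop("data contains no columns matching the chain's species")
  time_s <- as.numeric(data$time_s)
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  obs <- as.matrix(data[pools])
  n_par <- length(system$species) - 1L
  init <- rep_len(init, n_par)
  lower <- rep_len(lower, n_par)
  upper <- rep_len(upper, n_par)
  init <- pmin(pmax(init, lower), upper)
  grid <- if (time_s[1L] > 0) c(0, time_s) else time_s
  sim_pools <- function(theta) {
    # the optimizer may probe the lower bound; a zero step constant is the
    # no-reaction limit, represented by a negligible positive rate
    rates_abs <- rescale_constants(pmax(theta, 1e-12), scheme)
    traj <- simulate_chain(system, rates_abs, profile, grid, rtol = rtol,
                           atol = atol)
    traj$states[match(time_s, traj$times), pools, drop = FALSE]
  }
  res_fn <- function(theta) as.vector(obs - sim_pools(theta))
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-13, ptol = 1e-13))
  theta_hat <- fit$par
  rates_hat <- rescale_constants(theta_hat, scheme)
  n <- length(res_fn(theta_hat))
  df <- n - n_par
  ci_star <- rep(NA_real_, n_par)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, n_par))
  if (all(is.finite(se)) && df > 0)
    ci_star <- se * stats::qt(0.975, df = df)
  ci_abs <- rescale_constants(ci_star, scheme)
  pred <- sim_pools(theta_hat)
  per_pool <- lapply(pools, function(p)
    tryCatch(goodness_stats(pred[, p], obs[, p]), error = function(e) NULL))
  names(per_pool) <- pools
  overall <- goodness_stats(as.vector(pred), as.vector(obs))
  step_names <- paste0("k", seq_len(n_par))
  make_fit_result(
    estimates = c(stats::setNames(as.list(rates_hat), step_names),
                  list(dimensionless = stats::setNames(theta_hat,
                                                       step_names))),
    ci95 = stats::setNames(as.list(ci_abs), step_names),
    stats = c(per_pool, list(overall = overall)),
    convergence = list(iterations = fit$niter, cost = fit$deviance,
                       success = fit$info %in% 1:4, message = fit$message))
}

#' Sensitivity of the predicted parent profile to the proportionality factor
#'
#' Re-simulates the parent profile with `k_prop` multiplied by each factor
#' and reports the maximum deviation from the base profile over the grid,
#' both relative (`|pert - base| / base`) and absolute.
#'
#' @param system a [chain_system()].
#' @param rates absolute per-step constants in 1/(M s).
#' @param profile the base [oh_profile()].
#' @param multipliers positive multipliers on `k_prop` (default one order of
#'   magnitude down and up).
#' @param t_grid evaluation grid in seconds.
#' @param ... passed to [simulate_chain()].
#' @return data frame with columns `multiplier`, `max_rel_dev`,
#'   `max_abs_dev`.
#' @export
sensitivity_in_k <- function(system, rates, profile,
                             multipliers = c(0.1, 10), t_grid, ...) {
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  parent <- system$species[1L]
  base <- simulate_chain(system, rates, profile, t_grid, ...)$states[, parent]
  out <- data.frame(multiplier = multipliers, max_rel_dev = NA_real_,
                    max_abs_dev = NA_real_)
  for (i in seq_along(multipliers)) {
    prof_i <- oh_profile(profile$poly, profile$k_prop * multipliers[i],
                         profile$reference_conc)
    pert <- simulate_chain(system, rates, prof_i, t_grid, ...)$states[, parent]
    dev <- abs(pert - base)
    out$max_abs_dev[i] <- max(dev)
    out$max_rel_dev[i] <- max(dev / base)
  }
  out
}
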