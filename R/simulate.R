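#' Integrate the lumped chain under a hydroxyl-radical profile
#'
#' Solves the normalized chain equations in absolute time with an adaptive
#' explicit Runge-Kutta 4(5) method. The absolute radical concentration
#' driving every step is `[.OH](t) = C0 * k_prop * H2O2*(t)`, so absolute
#' second-order constants (1/(M s)) are used directly; this is mathematically
#' identical to integrating the dimensionless form. Mass balance and pool
#' non-negativity are verified after integration as a post-check, not
#' enforced as a constraint.
#'
#' @param system a [chain_system()].
#' @param rates absolute per-step constants in 1/(M s) (length pools - 1).
#' @param profile an [oh_profile()] whose `reference_conc` matches the
#'   system's C0.
#' @param t_grid output times in seconds, increasing, inside the profile
#'   domain.
#' @param rtol,atol relative and absolute solver tolerances. Pools span
#'   several orders of magnitude in normalized units at late times, hence the
#'   tight defaults.
#' @return an object of class `chain_trajectory`: list with `times`, `states`
#'   (matrix, one column per pool, rows clipped to be >= 0), `system`,
#'   `rates`, `k_prop`.
#' @export
simulate_chain <- function(system, rates, profile, t_grid,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "chain_system"), inherits(profile, "oh_profile"))
  n <- length(system$species)
  rates <- check_rates(rates, n)
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (min(t_grid) < 0 || max(t_grid) > profile$poly$t_max_s)
    stop("t_grid outside the radical profile's valid domain")
  c0 <- system$c0_mol_L
  cf <- profile$poly$coefficients
  deriv <- function(t, y, parms) {
    oh_abs <- c0 * profile$k_prop * max(poly_value(cf, t), 0)
    list(chain_rhs(y, oh_abs, rates))
  }
  times <- if (t_grid[1L] > 0) c(0, t_grid) else t_grid
  t_end <- max(times)
  # the clamped polynomial has derivative kinks at its sign changes; the
  # integration is restarted there so no adaptive step straddles a kink
  breaks <- numeric(0)
  if (length(cf) > 1L && any(cf[-1L] != 0)) {
    rts <- polyroot(cf)
    re <- Re(rts)[abs(Im(rts)) < 1e-8 * pmax(abs(Re(rts)), 1)]
    breaks <- sort(re[re > times[1L] & re < t_end])
  }
  bounds <- unique(c(times[1L], breaks, t_end))
  n_states <- length(system$initial_state)
  states_req <- matrix(NA_real_, length(times), n_states)
  y <- unname(system$initial_state)
  states_req[match(times[1L], times), ] <- y
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    inner <- times[times > a & times <= b]
    tt <- unique(c(a, inner, b))
    sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] != 2 && attr(sol, "istate")[1L] != 0) {
      diag <- utils::capture.output(deSolve::diagnostics(sol))
      stop("ODE integration failed:\n", paste(diag, collapse = "\n"))
    }
    y <- unname(sol[nrow(sol), -1L])
    if (length(inner))
      states_req[match(inner, times), ] <- sol[match(inner, tt), -1L]
  }
  states <- states_req[match(t_grid, times), , drop = FALSE]
  bal <- abs(rowSums(states) - sum(system$initial_state))
  if (any(bal > 1e-6))
    stop("mass-balance violated after integration (max deviation ",
         format(max(bal)), "); tighten rtol/atol")
  if (any(states < -1e-9))
    stop("negative pool values beyond tolerance after integration")
  states[states < 0] <- 0
  colnames(states) <- system$species
  structure(list(times = t_grid, states = states, system = system,
                 rates = rates, k_prop = profile$k_prop),
            class = "chain_trajectory")
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat("Chain trajectory:", length(x$times), "time points, pools",
      paste(colnames(x$states), collapse = ", "), "\n")
  cat("  t in [", min(x$times), ",", max(x$times), "] s; k_prop =",
      format(x$k_prop), "\n")
  invisible(x)
}

# linearly interpolated normalized state at time t (named vector)
traj_state <- function(traj, t) {
  stopifnot(inherits(traj, "chain_trajectory"))
  if (length(t) != 1L || t < min(traj$times) || t > max(traj$times))
    stop("t outside the trajectory's time range")
  out <- vapply(seq_len(ncol(traj$states)), function(i)
    stats::approx(traj$times, traj$states[, i], xout = t)$y, numeric(1))
  stats::setNames(out, colnames(traj$states))
}

#' Fractional removal of a pool at time t
#'
#' `1 - pool(t) / pool(0)`, clipped to `[0, 1]`.
#'
#' @param traj a `chain_trajectory`.
#' @param pool pool label (default: the parent, first pool).
#' @param t evaluation time in seconds.
#' @return removal fraction in `[0, 1]`.
#' @export
removal_fraction <- function(traj, pool = colnames(traj$states)[1L], t) {
  s0 <- traj$system$initial_state[[pool]]
  if (is.null(s0) || s0 <= 0)
    stop("pool '", pool, "' has zero initial mass; removal is undefined")
  val <- traj_state(traj, t)[[pool]]
  min(max(1 - val / s0, 0), 1)
}

#' Mineralization fraction at time t
#'
#' Value of the terminal (CO2) pool: the fraction of the initial organic
#' carbon fully oxidized to CO2 and water.
#'
#' @inheritParams removal_fraction
#' @return mineralization fraction in `[0, 1]`.
#' @export
mineralization_fraction <- function(traj, t) {
  terminal <- colnames(traj$states)[ncol(traj$states)]
  min(max(traj_state(traj, t)[[terminal]], 0), 1)
}

#' Turnover of the cumulatively formed amount of an intermediate
#'
#' An intermediate pool both forms and degrades, so its net level understates
#' how much of it has been processed. The cumulative inflow into pool i up to
#' time t equals the net increase of pool i plus all pools downstream of it;
#' the turnover is the fraction of that formed amount that has already been
#' oxidized further: `1 - pool(t) / cumulative_inflow(t)`.
#'
#' @param traj a `chain_trajectory`.
#' @param pool label of an intermediate (neither first nor last) pool.
#' @param t evaluation time in seconds.
#' @return turnover fraction in `[0, 1]`.
#' @export
formed_intermediate_turnover <- function(traj, pool, t) {
  labs <- colnames(traj$states)
  i <- match(pool, labs)
  if (is.na(i) || i == 1L || i == length(labs))
    stop("pool must be an intermediate (not the parent or the terminal pool)")
  st <- traj_state(traj, t)
  init <- traj$system$initial_state
  inflow <- sum(st[i:length(labs)] - init[i:length(labs)])
  if (inflow <= 0)
    stop("no cumulative inflow into '", pool, "' at t = ", t,
         "; turnover is undefined")
  min(max(1 - st[[pool]] / inflow, 0), 1)
}

#' Simulate the chain across current densities
#'
#' One trajectory per requested current density, with the proportionality
#' factor taken from the linear current-density law; the H2O2 polynomial
#' shape is shared across densities, only its radical yield scales.
#'
#' @param system a [chain_system()].
#' @param rates absolute per-step constants in 1/(M s).
#' @param poly the shared [h2o2_poly()].
#' @param law a [current_density_law()].
#' @param j_values current densities in mA/cm^2, all > 0.
#' @param t_grid output times in seconds.
#' @param ... passed to [simulate_chain()] (`rtol`, `atol`).
#' @return named list of `chain_trajectory` objects, one per `j`.
#' @export
sweep_current_density <- function(system, rates, poly, law, j_values, t_grid,
                                  ...) {
  if (any(j_values <= 0)) stop("all current densities must be > 0")
  out <- lapply(j_values, function(j) {
    prof <- oh_profile(poly, k_of_j(law, j), system$c0_mol_L)
    simulate_chain(system, rates, prof, t_grid, ...)
  })
  names(out) <- as.character(j_values)
  out
}

#' Summarize a current-density sweep at one evaluation time
#'
#' @param sweeps result of [sweep_current_density()].
#' @param t evaluation time in seconds.
#' @param potencies optional named potency vector (see [pool_potencies()]);
#'   when given, the toxic-unit reduction at `t` is included.
#' @return data frame with one row per current density: `j`, `removal`,
#'   `mineralization`, and optionally `toxicity_reduction` (all fractions
#'   except the last, a percentage).
#' @export
sweep_summary <- function(sweeps, t, potencies = NULL) {
  out <- data.frame(j = as.numeric(names(sweeps)),
                    removal = NA_real_, mineralization = NA_real_)
  if (!is.null(potencies)) out$toxicity_reduction <- NA_real_
  for (i in seq_along(sweeps)) {
    traj <- sweeps[[i]]
    out$removal[i] <- removal_fraction(traj, t = t)
    out$mineralization[i] <- mineralization_fraction(traj, t)
    if (!is.null(potencies)) {
      tox <- toxicity_profile(traj, potencies)
      out$toxicity_reduction[i] <-
        100 - stats::approx(traj$times, tox, xout = t)$y
    }
  }
  out
}
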