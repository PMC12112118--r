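#' Define a lumped sequential oxidation chain
#'
#' A chain system describes the ordered pools of a lumped degradation
#' mechanism: the parent pollutant first, one or more lumped intermediate
#' pools, and the terminal mineral end-product (CO2) last. Each step is a
#' second-order reaction of the pool with the hydroxyl radical; pool
#' concentrations are carried in the normalized frame (divided by the parent's
#' initial molar concentration), so a fresh solution is `(1, 0, ..., 0)`.
#'
#' @param species character vector of pool labels, parent first, terminal
#'   mineral pool (CO2) last. At least three pools.
#' @param c0_mol_L initial molar concentration of the parent pollutant (mol/L).
#' @param initial_state optional normalized initial pool vector; entries must
#'   be non-negative and sum to 1. Defaults to all mass in the parent pool.
#' @param lump_members optional named list mapping intermediate pool labels to
#'   data frames of the identified compounds they lump (columns `name`,
#'   `molar_mass_g_mol`, `lc50_mg_L`); used by the toxicity module.
#' @return an object of class `chain_system`.
#' @seealso [chain_rhs()], [simulate_chain()], [bateman_chain()]
#' @export
chain_system <- function(species, c0_mol_L, initial_state = NULL,
                         lump_members = NULL) {
  species <- as.character(species)
  n <- length(species)
  if (n < 3L)
    stop("a chain system needs at least 3 pools (parent, intermediate(s), CO2)")
  if (anyDuplicated(species))
    stop("pool labels must be unique")
  if (!is.numeric(c0_mol_L) || length(c0_mol_L) != 1L || !is.finite(c0_mol_L) ||
      c0_mol_L <= 0)
    stop("c0_mol_L must be a single positive number (mol/L)")
  if (is.null(initial_state)) initial_state <- c(1, rep(0, n - 1L))
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != n)
    stop("initial_state must have one entry per pool")
  if (any(initial_state < 0))
    stop("initial_state entries must be non-negative")
  if (abs(sum(initial_state) - 1) > 1e-12)
    stop("initial_state must sum to 1 (normalized concentrations)")
  if (!is.null(lump_members)) {
    if (!all(names(lump_members) %in% species[-c(1L, n)]))
      stop("lump_members names must be intermediate pool labels")
  }
  structure(list(species = species,
                 c0_mol_L = c0_mol_L,
                 initial_state = stats::setNames(initial_state, species),
                 lump_members = lump_members),
            class = "chain_system")
}

#' @export
print.chain_system <- function(x, ...) {
  cat("Lumped oxidation chain:", paste(x$species, collapse = " -> "), "\n")
  cat("  parent C0 =", format(x$c0_mol_L), "mol/L\n")
  cat("  initial normalized state:",
      paste(format(unname(x$initial_state)), collapse = ", "), "\n")
  invisible(x)
}

# validate a vector of per-step rate constants against a chain of n pools
check_rates <- function(rates, n_pools) {
  rates <- as.numeric(rates)
  if (length(rates) != n_pools - 1L)
    stop("need one rate constant per chain step (pools - 1 = ",
         n_pools - 1L, "), got ", length(rates))
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be finite and > 0")
  rates
}

#' Normalization scheme linking dimensionless and absolute rate constants
#'
#' The model is fitted in a dimensionless frame: concentrations are divided by
#' the parent's initial molar concentration and time by a fixed scaling factor.
#' A dimensionless step constant `k*` maps back to the absolute second-order
#' constant as `k = k* / (scaling_s * reference_conc)`, in 1/(M s).
#'
#' @param scaling_s time scale in seconds used to non-dimensionalize time
#'   (default `1e-6` s).
#' @param reference_conc parent initial concentration C0 in mol/L.
#' @return an object of class `normalization_scheme`.
#' @export
normalization_scheme <- function(scaling_s = 1e-6, reference_conc) {
  if (!is.numeric(scaling_s) || length(scaling_s) != 1L || scaling_s <= 0 ||
      !is.finite(scaling_s))
    stop("scaling_s must be a single positive number (seconds)")
  if (!is.numeric(reference_conc) || length(reference_conc) != 1L ||
      reference_conc <= 0 || !is.finite(reference_conc))
    stop("reference_conc must be a single positive number (mol/L)")
  structure(list(scaling_s = scaling_s, reference_conc = reference_conc),
            class = "normalization_scheme")
}

#' Right-hand side of the normalized lumped-chain rate equations
#'
#' Evaluates the time derivative of the normalized pool vector for a
#' sequential chain driven by a normalized hydroxyl-radical level: the parent
#' pool is consumed at `k1* * parent * oh_star`, each intermediate gains the
#' outflow of its upstream pool and loses its own, and the terminal pool only
#' accumulates. The derivatives sum to zero exactly (mass balance).
#'
#' @param state normalized pool vector (length = number of pools).
#' @param oh_star normalized hydroxyl-radical level, >= 0.
#' @param rates_star per-step rate constants in the same frame as `state` and
#'   the time unit of the caller (length = pools - 1).
#' @return numeric derivative vector, same length as `state`.
#' @export
chain_rhs <- function(state, oh_star, rates_star) {
  n <- length(state)
  if (length(rates_star) != n - 1L)
    stop("length(state) must equal length(rates_star) + 1")
  if (!is.numeric(oh_star) || length(oh_star) != 1L || oh_star < 0)
    stop("oh_star must be a single non-negative number")
  flux <- rates_star * state[-n] * oh_star
  # inflow - outflow per pool; the terminal pool receives the last step only.
  # It is assembled as minus the sum of the other derivatives — equal to
  # flux[n-1] in exact arithmetic — so conservation holds exactly in
  # floating point too.
  d <- c(-flux[1L],
         if (n > 2L) flux[-(n - 1L)] - flux[-1L],
         0)
  d[n] <- -sum(d[-n])
  d
}

#' Convert dimensionless rate constants to absolute second-order constants
#'
#' @param rates_star dimensionless per-step constants.
#' @param scheme a [normalization_scheme()].
#' @return absolute constants in 1/(M s).
#' @export
rescale_constants <- function(rates_star, scheme) {
  stopifnot(inherits(scheme, "normalization_scheme"))
  as.numeric(rates_star) / (scheme$scaling_s * scheme$reference_conc)
}

#' Convert absolute second-order constants to the dimensionless frame
#'
#' Inverse of [rescale_constants()]; the round trip is exact to floating
#' precision.
#'
#' @param rates absolute constants in 1/(M s).
#' @inheritParams rescale_constants
#' @return dimensionless per-step constants.
#' @export
unscale_constants <- function(rates, scheme) {
  stopifnot(inherits(scheme, "normalization_scheme"))
  as.numeric(rates) * (scheme$scaling_s * scheme$reference_conc)
}

# ---- closed-form (Bateman) solution of the chain in the exposure variable ---
#
# With u(t) = integral of the absolute radical concentration (M s), the chain
# is linear with constant coefficients in u, and each pool is a sum of
# exp(-k u) terms (classical Bateman solution). Repeated rates give confluent
# terms u^m exp(-k u); both cases are handled through partial fractions of
# 1 / prod(s + kappa_l), with higher-order poles for groups of (numerically)
# equal rates, so no division by a vanishing rate difference ever occurs.

# group decay rates into distinct values with multiplicities
group_rates <- function(kappa, rel_tol = 1e-9) {
  lambda <- numeric(0)
  mult <- integer(0)
  for (x in kappa) {
    hit <- FALSE
    for (g in seq_along(lambda)) {
      sc <- max(abs(lambda[g]), abs(x), 1e-300)
      if (abs(x - lambda[g]) <= rel_tol * sc) {
        mult[g] <- mult[g] + 1L
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      lambda <- c(lambda, x)
      mult <- c(mult, 1L)
    }
  }
  list(lambda = lambda, mult = mult)
}

# inverse Laplace transform of 1 / prod_r (s + lambda_r)^mult_r, vectorized
# over u. Partial-fraction coefficients at each pole come from derivatives of
# g(s) = prod_{r' != r} (s + lambda_r')^(-m_r'), computed by the recursion
# g' = g * phi with phi(s) = sum -m'/(s + lambda').
inv_laplace_poles <- function(u, lambda, mult) {
  out <- numeric(length(u))
  for (r in seq_along(lambda)) {
    m <- mult[r]
    s0 <- -lambda[r]
    lo <- lambda[-r]
    mo <- mult[-r]
    g <- numeric(m)                       # g[q+1] = g^(q)(s0)
    g[1L] <- if (length(lo)) prod((s0 + lo)^(-mo)) else 1
    if (m > 1L) {
      phi <- vapply(0:(m - 2L), function(q)
        if (length(lo))
          sum(-mo * (-1)^q * factorial(q) / (s0 + lo)^(q + 1)) else 0,
        numeric(1))
      for (p in 1:(m - 1L))
        g[p + 1L] <- sum(choose(p - 1L, 0:(p - 1L)) * g[1:p] *
                           phi[p - (0:(p - 1L))])
    }
    for (q in 0:(m - 1L)) {
      pole_order <- m - q
      out <- out + g[q + 1L] / factorial(q) *
        u^(pole_order - 1L) * exp(-lambda[r] * u) / factorial(pole_order - 1L)
    }
  }
  out
}

#' Exact chain solution at a given hydroxyl-radical exposure
#'
#' Closed-form (Bateman) solution of the sequential chain evaluated at the
#' radical exposure `u = integral of [.OH] dt` (M s). Because the chain is
#' linear in each pool once the radical profile is fixed, the solution in the
#' exposure variable is exact for *any* non-negative radical profile; it is
#' the package's independent oracle against which numerical trajectories are
#' verified. Repeated step constants are handled by the confluent-limit
#' branch (terms `u^m exp(-k u)`), not by division by rate differences.
#'
#' @param exposure radical exposure(s) `u` in M s; non-negative, may be a
#'   vector.
#' @param rates absolute per-step second-order constants in 1/(M s).
#' @param initial_state normalized pool vector at `u = 0`.
#' @return for a single exposure, a named numeric pool vector; for several, a
#'   matrix with one row per exposure.
#' @export
bateman_chain <- function(exposure, rates, initial_state) {
  if (any(exposure < 0)) stop("exposure must be non-negative")
  n <- length(initial_state)
  rates <- check_rates(rates, n)
  kappa <- c(rates, 0)                    # terminal pool does not decay
  res <- matrix(0, length(exposure), n)
  for (j in seq_len(n)) {
    if (initial_state[j] == 0) next
    for (i in j:n) {
      prefactor <- if (i > j) prod(rates[j:(i - 1L)]) else 1
      gr <- group_rates(kappa[j:i])
      res[, i] <- res[, i] + initial_state[j] * prefactor *
        inv_laplace_poles(exposure, gr$lambda, gr$mult)
    }
  }
  if (!is.null(names(initial_state))) colnames(res) <- names(initial_state)
  if (length(exposure) == 1L) res[1L, ] else res
}
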