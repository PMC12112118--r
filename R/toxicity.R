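#' Read a table of per-compound toxicity records
#'
#' Records carry the molar mass (g/mol) and the 96-h Fathead Minnow LC50
#' (mg/L) of each identified compound, plus the lumped pool each compound is
#' assigned to. The packaged table for the bisphenol A system ships as
#' `table1_lc50.csv` in `inst/extdata`.
#'
#' @param path CSV file with columns `name`, `pool`, `molar_mass_g_mol`,
#'   `lc50_mg_L`. Defaults to the packaged bisphenol A table.
#' @return data frame of toxicity records.
#' @export
read_tox_records <- function(path = system.file("extdata", "table1_lc50.csv",
                                                package = "ohkin")) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "pool", "molar_mass_g_mol", "lc50_mg_L")
  if (!all(need %in% names(rec)))
    stop("toxicity table must have columns: ", paste(need, collapse = ", "))
  if (any(rec$molar_mass_g_mol <= 0) || any(rec$lc50_mg_L <= 0))
    stop("molar masses and LC50 values must be positive")
  rec
}

# mass potency of one compound: M / LC50 (toxic units per mole, up to the
# common volume factor that cancels in the normalized ratio)
tox_potency <- function(molar_mass_g_mol, lc50_mg_L) {
  molar_mass_g_mol / lc50_mg_L
}

#' Aggregate member potencies into a lumped-pool potency
#'
#' A lumped pool groups several identified compounds; its effective potency
#' `p = M / LC50` is an aggregate of the member potencies. The mechanism
#' gives no composition within a pool, so the arithmetic mean (default) is
#' used; `min`/`max` bracket the optimistic and conservative readings.
#'
#' @param members data frame with columns `molar_mass_g_mol` and `lc50_mg_L`
#'   (at least one row).
#' @param method one of `"mean"`, `"min"`, `"max"`.
#' @return scalar pool potency.
#' @export
lump_potency <- function(members, method = c("mean", "min", "max")) {
  method <- match.arg(method)
  if (is.null(nrow(members)) || nrow(members) < 1L)
    stop("a lumped pool needs at least one member compound")
  p <- tox_potency(members$molar_mass_g_mol, members$lc50_mg_L)
  switch(method, mean = mean(p), min = min(p), max = max(p))
}

#' Per-pool potencies for a chain system
#'
#' Builds the named potency vector used by [toxicity_profile()]: the parent
#' pool takes its own compound's potency, each intermediate pool the
#' aggregated potency of its member compounds, and the terminal CO2 pool a
#' potency of zero (mineral end products are non-toxic by construction).
#'
#' @param records toxicity records as from [read_tox_records()]; the `pool`
#'   column assigns compounds to chain pools.
#' @param species ordered pool labels of the chain.
#' @param method aggregation method passed to [lump_potency()].
#' @return named numeric vector of potencies, one per pool.
#' @export
pool_potencies <- function(records, species, method = "mean") {
  n <- length(species)
  p <- stats::setNames(numeric(n), species)
  for (i in seq_len(n - 1L)) {
    members <- records[records$pool == species[i], , drop = FALSE]
    if (nrow(members) == 0L)
      stop("no toxicity records assigned to pool '", species[i], "'")
    p[i] <- lump_potency(members, method = method)
  }
  p[n] <- 0
  p
}

#' Time-dependent relative toxicity of the treated mixture
#'
#' Toxic-unit sum normalized to the untreated parent: each pool contributes
#' its normalized concentration times its mass potency `M/LC50`, and the sum
#' is expressed as a percentage of the parent's initial toxic units,
#' `Toxicity%(t) = 100 * sum_i pool_i*(t) p_i / p_parent`. A fresh solution
#' (all mass in the parent) reads exactly 100%; a fully mineralized one 0%.
#' Only potency ratios enter, so a common rescaling of all LC50 values leaves
#' the profile unchanged.
#'
#' @param traj a `chain_trajectory`.
#' @param potencies named potency vector aligned with the trajectory's pools
#'   (see [pool_potencies()]).
#' @param reference_potency potency used for normalization; defaults to the
#'   parent pool's.
#' @return numeric vector of toxicity percentages along `traj$times`.
#' @export
toxicity_profile <- function(traj, potencies,
                             reference_potency = potencies[[1L]]) {
  stopifnot(inherits(traj, "chain_trajectory"))
  labs <- colnames(traj$states)
  if (is.null(names(potencies)) || !identical(names(potencies), labs))
    stop("potencies must be named exactly as the trajectory's pools, ",
         "in order: ", paste(labs, collapse = ", "))
  if (reference_potency <= 0) stop("reference potency must be > 0")
  as.vector(100 * (traj$states %*% potencies) / reference_potency)
}

#' Summary of a toxicity time profile
#'
#' The characteristic shape under increasing oxidation is biphasic: an early
#' rise while toxic early intermediates accumulate, an interior maximum, then
#' a decline towards mineralization. The peak is located by discrete argmax
#' with the earlier time winning ties.
#'
#' @param toxicity toxicity percentages (>= 3 points).
#' @param times matching times in seconds.
#' @return list with `peak`, `peak_time`, `reduction_at_end`
#'   (`100 - toxicity at the last time`).
#' @export
toxicity_summary <- function(toxicity, times) {
  if (length(toxicity) != length(times) || length(toxicity) < 3L)
    stop("need matching toxicity/times vectors with at least 3 points")
  i <- which.max(toxicity)            # which.max takes the earliest maximum
  list(peak = toxicity[i], peak_time = times[i],
       reduction_at_end = 100 - toxicity[length(toxicity)])
}
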