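#' Substrate degradation rate
#'
#' Fraction of the initial substrate consumed over the batch,
#' (initial - final) / initial. Both arguments are mass concentrations in
#' g L^-1; the result is a dimensionless fraction in \[0, 1\]
#' (multiply by 100 for the percent form used in reporting).
#'
#' @param initial Initial substrate concentration, g L^-1. Must be > 0.
#' @param final Final substrate concentration, g L^-1. Must satisfy
#'   `0 <= final <= initial`.
#' @return Consumed fraction (dimensionless), vectorised over its arguments.
#' @examples
#' consumption_rate(4, 3.54) # ~11.5 % consumed
#' @export
consumption_rate <- function(initial, final) {
  stopifnot(is.numeric(initial), is.numeric(final))
  if (any(initial <= 0)) abort("initial substrate must be > 0")
  if (any(final < 0)) abort("final substrate must be >= 0")
  if (any(final > initial)) abort("negative consumption: final exceeds initial")
  (initial - final) / initial
}

#' Consumed substrate as a molar concentration
#'
#' Converts a consumed fraction of the initial substrate mass concentration
#' to micromoles per litre, the unit in which metabolite panels are recorded.
#'
#' @param initial Initial substrate concentration, g L^-1.
#' @param fraction Consumed fraction in \[0, 1\].
#' @param molar_mass Substrate molar mass, g mol^-1 (xylose 150.13).
#' @return Consumed substrate, umol L^-1.
#' @examples
#' consumed_molar_conc(4, 0.115) # ~3064 umol/L xylose
#' @export
consumed_molar_conc <- function(initial, fraction, molar_mass = xylose_molar_mass()) {
  stopifnot(is.numeric(initial), is.numeric(fraction), molar_mass > 0)
  if (any(fraction < 0 | fraction > 1)) abort("consumed fraction must lie in [0, 1]")
  if (any(initial <= 0)) abort("initial substrate must be > 0")
  fraction * initial / molar_mass * 1e6
}

#' Coulombs embodied in a metabolite concentration change
#'
#' Charge attributed to a product (or to the substrate) from its molar
#' concentration change: C = F * b * V * dC, where b is the species'
#' net electron bookkeeping (`coulomb_b` in [species_constants()]) and
#' F the Faraday constant. `delta_conc` is supplied directly as a molar
#' concentration change in umol L^-1; no molar-mass division is applied.
#'
#' @param delta_conc Concentration change, umol L^-1 (>= 0).
#' @param volume Reactor liquid volume, litres.
#' @param species One of `"xylose"`, `"ethanol"`, `"acetate"`, `"hydrogen"`.
#' @return Charge in coulombs, vectorised over `delta_conc`/`species`.
#' @examples
#' coulombs_from_metabolite(2093, 0.1, "ethanol") # ~69 C
#' @export
coulombs_from_metabolite <- function(delta_conc, volume, species) {
  stopifnot(is.numeric(delta_conc), is.numeric(volume))
  if (any(delta_conc < 0)) abort("concentration change must be >= 0")
  if (any(volume <= 0)) abort("volume must be > 0")
  b <- species_constant(species, "coulomb_b")
  faraday_constant() * b * volume * delta_conc * 1e-6
}

#' Coulombs consumed by measured hydrogen production
#'
#' Two electrons per mole of H2: C = 2 * F * n.
#'
#' @param n_h2 Amount of hydrogen produced, umol (absolute amount, not a
#'   concentration).
#' @return Charge in coulombs.
#' @examples
#' coulombs_from_h2(0.11) # ~0.021 C
#' @export
coulombs_from_h2 <- function(n_h2) {
  stopifnot(is.numeric(n_h2))
  if (any(n_h2 < 0)) abort("hydrogen amount must be >= 0")
  2 * faraday_constant() * n_h2 * 1e-6
}

#' Charge recovered as current: trapezoidal integral of a trace
#'
#' Integrates a chronoamperometry trace I(t) from its first to its last
#' sample by the trapezoidal rule, with time converted from hours to
#' seconds. The sign of the current is preserved, so a net-negative trace
#' yields a negative charge. No resampling or smoothing is applied.
#'
#' @param trace Data frame with columns `time_h` (hours, strictly
#'   increasing) and `current_A` (amperes). At least two samples.
#' @return Charge in coulombs.
#' @examples
#' tr <- data.frame(time_h = c(0, 150), current_A = c(1e-6, 1e-6))
#' integrate_current(tr) # 0.54 C
#' @export
integrate_current <- function(trace) {
  trace <- check_trace(trace)
  if (nrow(trace) < 2) abort("trace needs at least 2 samples")
  pracma::trapz(trace$time_h * 3600, trace$current_A)
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_h", "current_A") %in% names(trace))) {
    abort("trace must be a data frame with columns time_h and current_A")
  }
  if (nrow(trace) == 0) abort("empty trace")
  if (anyNA(trace$time_h) || anyNA(trace$current_A)) abort("trace contains NA")
  if (any(diff(trace$time_h) <= 0)) abort("trace times must be strictly increasing")
  tibble::as_tibble(trace[c("time_h", "current_A")])
}

#' Coulombic efficiency
#'
#' Charge recovered as current divided by the charge theoretically
#' available from the consumed substrate:
#' CE = |C_I| / (F * b * n_consumed) * 100, with n_consumed =
#' consumed mass / molar mass. The magnitude of `c_i` is used so that a
#' reactor with net-negative charge still reports a positive efficiency.
#'
#' @param c_i Integrated charge, coulombs (sign ignored).
#' @param consumed_mass Substrate mass consumed in the reactor, grams (> 0).
#' @param molar_mass Substrate molar mass, g mol^-1.
#' @param b_substrate Electrons per mole of substrate on full oxidation
#'   (20 for xylose).
#' @return Coulombic efficiency, percent.
#' @examples
#' coulombic_efficiency(1.06, 0.046) # ~0.18 %
#' @export
coulombic_efficiency <- function(c_i, consumed_mass,
                                 molar_mass = xylose_molar_mass(),
                                 b_substrate = 20) {
  stopifnot(is.numeric(c_i), is.numeric(consumed_mass))
  if (any(consumed_mass <= 0)) abort("undefined CE: no substrate consumed")
  abs(c_i) / (faraday_constant() * b_substrate * consumed_mass / molar_mass) * 100
}

#' Cathodic gas recovery
#'
#' Charge embodied in the recovered hydrogen divided by the charge that
#' arrived at the cathode as current: r_CAT = C_H2 / |C_I| * 100.
#'
#' @param c_h2 Charge embodied in produced H2, coulombs.
#' @param c_i Integrated charge, coulombs; must be non-zero (sign ignored).
#' @return Recovery, percent.
#' @examples
#' cathodic_gas_recovery(coulombs_from_h2(0.11), 1.06) # ~2 %
#' @export
cathodic_gas_recovery <- function(c_h2, c_i) {
  stopifnot(is.numeric(c_h2), is.numeric(c_i))
  if (any(c_i == 0)) abort("no charge transferred: C_I is zero")
  c_h2 / abs(c_i) * 100
}

#' Product yield per mole of substrate consumed
#'
#' Simple molar ratio of a product to the substrate consumed over the
#' batch (not the substrate initially supplied).
#'
#' @param product_conc Product concentration, umol L^-1.
#' @param consumed_substrate_conc Substrate consumed, umol L^-1 (> 0).
#' @return Yield, mol product per mol substrate consumed.
#' @examples
#' product_yield(2000, consumed_molar_conc(4, 0.115)) # ~0.65 mol/mol
#' @export
product_yield <- function(product_conc, consumed_substrate_conc) {
  stopifnot(is.numeric(product_conc), is.numeric(consumed_substrate_conc))
  if (any(product_conc < 0)) abort("product concentration must be >= 0")
  if (any(consumed_substrate_conc <= 0)) abort("yield undefined: no substrate consumed")
  product_conc / consumed_substrate_conc
}

panel_pools <- function(panel, pools) {
  vapply(pools, function(p) {
    v <- panel[[p]]
    if (is.null(v) || length(v) == 0 || is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
}

#' Carbon partition of the consumed substrate
#'
#' Distributes the carbon of the consumed substrate over the measured
#' carbon-bearing pools. Each pool's share is
#' carbon_atoms(pool) * conc(pool) / (5 * consumed) * 100 percent; the
#' carbon conversion efficiency (CCE) is the sum of the assigned shares,
#' and `unaccounted` is its complement (flagged if negative). Hydrogen
#' carries no carbon and does not appear.
#'
#' @param panel Named list or one-row data frame with entries `ethanol`,
#'   `acetate` (umol L^-1) and optionally `biomass` (umol L^-1 of C5H7O2N).
#'   Missing entries count as zero.
#' @param consumed_substrate_conc Substrate consumed, umol L^-1 (> 0).
#' @return A tibble with columns `pool` (ethanol, acetate, biomass,
#'   unaccounted) and `share_pct`.
#' @examples
#' carbon_shares(list(ethanol = 2000, acetate = 1874),
#'               consumed_molar_conc(4, 0.115))
#' @export
carbon_shares <- function(panel, consumed_substrate_conc) {
  if (any(consumed_substrate_conc <= 0)) abort("no substrate consumed")
  pools <- c("ethanol", "acetate", "biomass")
  conc <- panel_pools(panel, pools)
  atoms <- species_constant(pools, "carbon_atoms")
  share <- atoms * conc / (5 * consumed_substrate_conc) * 100
  tibble::tibble(
    pool = c(pools, "unaccounted"),
    share_pct = c(unname(share), 100 - sum(share))
  )
}

#' Electron partition of the consumed substrate
#'
#' Distributes the electron equivalents of the consumed substrate over the
#' measured pools using the full-oxidation convention
#' (`electron_equiv` in [species_constants()]): each dissolved pool's share
#' is equiv(pool) * conc(pool) / (20 * consumed) * 100 percent. Hydrogen is
#' recorded as an absolute amount (umol), so its moles are compared against
#' consumed-substrate moles = conc * volume. When an integrated charge is
#' supplied, the electrons exported as current are reported as
#' |C_I| / (F * 20 * moles consumed) * 100. The total electron conversion
#' efficiency (ECE) is the sum over products, biomass and H2;
#' `unaccounted` completes the partition to 100 %.
#'
#' @inheritParams carbon_shares
#' @param panel As in [carbon_shares()], plus optional `hydrogen` (umol).
#' @param c_i Optional integrated charge, coulombs (sign ignored); `NA` or
#'   `NULL` drops the current pool.
#' @param volume Reactor liquid volume, litres (needed for the hydrogen and
#'   current pools).
#' @return A tibble with columns `pool` (ethanol, acetate, hydrogen,
#'   biomass, current, unaccounted) and `share_pct`. The current share is
#'   informational and not part of the ECE sum.
#' @examples
#' electron_shares(list(ethanol = 2000, acetate = 1874, hydrogen = 0.11),
#'                 consumed_molar_conc(4, 0.115), c_i = 1.06, volume = 0.1)
#' @export
electron_shares <- function(panel, consumed_substrate_conc, c_i = NULL,
                            volume = 0.1) {
  if (any(consumed_substrate_conc <= 0)) abort("no substrate consumed")
  if (volume <= 0) abort("volume must be > 0")
  diss <- c("ethanol", "acetate", "biomass")
  conc <- panel_pools(panel, diss)
  eq <- species_constant(diss, "electron_equiv")
  denom_conc <- 20 * consumed_substrate_conc
  share_diss <- eq * conc / denom_conc * 100

  n_h2 <- panel_pools(panel, "hydrogen") # umol, absolute
  moles_consumed <- consumed_substrate_conc * 1e-6 * volume # mol
  share_h2 <- 2 * (n_h2 * 1e-6) / (20 * moles_consumed) * 100

  pools <- c("ethanol", "acetate", "hydrogen", "biomass")
  shares <- c(share_diss[1:2], share_h2, share_diss[3])
  out <- tibble::tibble(pool = pools, share_pct = unname(shares))
  if (!is.null(c_i) && !is.na(c_i)) {
    share_i <- abs(c_i) / (faraday_constant() * 20 * moles_consumed) * 100
    out <- dplyr::bind_rows(out, tibble::tibble(pool = "current", share_pct = share_i))
  }
  dplyr::bind_rows(
    out,
    tibble::tibble(pool = "unaccounted",
                   share_pct = 100 - sum(out$share_pct[out$pool != "current"]))
  )
}
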