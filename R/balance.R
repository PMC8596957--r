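#' Full electron/carbon balance of one reactor batch
#'
#' Composes the stoichiometric accounting for a single reactor run:
#' substrate consumption, per-product yields, per-pool coulombs, Coulombic
#' efficiency, cathodic gas recovery, and the carbon and electron
#' conversion-efficiency partitions.
#'
#' @param spec Named list or one-row data frame describing the reactor:
#'   `reactor_id`, `applied_potential` (volts vs SHE; `NA` for the
#'   no-potential control), `volume_l` (> 0), `initial_substrate`
#'   (g L^-1, > 0), `substrate_molar_mass` (g mol^-1, default xylose),
#'   `duration_h` (> 0).
#' @param panel Named list or one-row data frame: `ethanol`, `acetate`
#'   (umol L^-1), `hydrogen` (umol, absolute), optional `biomass`
#'   (umol L^-1 of C5H7O2N), and exactly one of `consumed_fraction`
#'   (in \[0, 1\]) or `substrate_final` (g L^-1).
#' @param trace Optional chronoamperometry trace (`time_h`, `current_A`);
#'   its trapezoidal integral supplies the charge C_I.
#' @param c_i Optional integrated charge in coulombs, used when no trace is
#'   available. Ignored if `trace` is given.
#' @return An object of class `balance_report`. Use [tidy()] for the
#'   per-pool share table and [glance()] for the one-row summary. CE and
#'   r_CAT are `NA` (not applicable) when no charge is available, as for a
#'   no-potential control.
#' @examples
#' rep <- balance_report(
#'   spec  = list(reactor_id = "+0.842 V", applied_potential = 0.842,
#'                volume_l = 0.1, initial_substrate = 4, duration_h = 150),
#'   panel = list(consumed_fraction = 0.115, ethanol = 2000,
#'                acetate = 1874, hydrogen = 0.11),
#'   c_i   = 1.06)
#' glance(rep)
#' @export
balance_report <- function(spec, panel, trace = NULL, c_i = NULL) {
  spec <- as.list(spec)
  panel <- as.list(panel)
  spec$substrate_molar_mass <- spec$substrate_molar_mass %||% xylose_molar_mass()
  for (f in c("volume_l", "initial_substrate", "duration_h")) {
    if (is.null(spec[[f]]) || !is.numeric(spec[[f]]) || spec[[f]] <= 0) {
      abort(paste0("reactor spec field '", f, "' must be a positive number"))
    }
  }

  has_fraction <- !is.null(panel$consumed_fraction) && !is.na(panel$consumed_fraction)
  has_final <- !is.null(panel$substrate_final) && !is.na(panel$substrate_final)
  if (has_fraction == has_final) {
    abort("panel must carry exactly one of consumed_fraction or substrate_final")
  }
  fraction <- if (has_fraction) {
    if (panel$consumed_fraction < 0 || panel$consumed_fraction > 1) {
      abort("consumed fraction must lie in [0, 1]")
    }
    panel$consumed_fraction
  } else {
    consumption_rate(spec$initial_substrate, panel$substrate_final)
  }

  consumed_conc <- consumed_molar_conc(spec$initial_substrate, fraction,
                                       spec$substrate_molar_mass)
  consumed_mass <- fraction * spec$initial_substrate * spec$volume_l

  if (!is.null(trace)) c_i <- integrate_current(trace)
  if (is.null(c_i)) c_i <- NA_real_

  conc <- panel_pools(panel, c("ethanol", "acetate", "biomass"))
  n_h2 <- unname(panel_pools(panel, "hydrogen"))

  yields <- tibble::tibble(
    species = c("ethanol", "acetate"),
    yield_mol_mol = if (consumed_conc > 0) {
      unname(product_yield(conc[c("ethanol", "acetate")], consumed_conc))
    } else c(NA_real_, NA_real_)
  )

  c_h2 <- coulombs_from_h2(n_h2)
  coulombs <- tibble::tibble(
    pool = c("ethanol", "acetate", "hydrogen", "substrate", "current"),
    coulombs = unname(c(
      coulombs_from_metabolite(conc["ethanol"], spec$volume_l, "ethanol"),
      coulombs_from_metabolite(conc["acetate"], spec$volume_l, "acetate"),
      c_h2,
      if (consumed_conc > 0) {
        coulombs_from_metabolite(consumed_conc, spec$volume_l, "xylose")
      } else 0,
      c_i
    ))
  )

  has_ci <- !is.na(c_i) && c_i != 0
  ce <- if (has_ci && consumed_mass > 0) {
    coulombic_efficiency(c_i, consumed_mass, spec$substrate_molar_mass)
  } else NA_real_
  r_cat <- if (has_ci) cathodic_gas_recovery(c_h2, c_i) else NA_real_

  if (consumed_conc > 0) {
    carbon <- carbon_shares(panel, consumed_conc)
    electron <- electron_shares(panel, consumed_conc,
                                c_i = if (has_ci) c_i else NULL,
                                volume = spec$volume_l)
  } else {
    carbon <- tibble::tibble(pool = character(), share_pct = numeric())
    electron <- carbon
  }
  assigned_c <- carbon$share_pct[carbon$pool != "unaccounted"]
  assigned_e <- electron$share_pct[!electron$pool %in% c("unaccounted", "current")]

  structure(list(
    reactor_id = spec$reactor_id %||% NA_character_,
    applied_potential = spec$applied_potential %||% NA_real_,
    consumption_fraction = fraction,
    consumption_pct = fraction * 100,
    consumed_conc = consumed_conc,
    consumed_mass = consumed_mass,
    yields = yields,
    coulombs = coulombs,
    ce_pct = ce,
    r_cat_pct = r_cat,
    carbon = carbon,
    electron = electron,
    cce_total = sum(assigned_c),
    ece_total = sum(assigned_e),
    overshoot = sum(assigned_c) > 100 || sum(assigned_e) > 100
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  pot <- if (is.na(x$applied_potential)) "no potential" else
    sprintf("%+.3f V vs SHE", x$applied_potential)
  cat(sprintf("<balance_report> reactor %s (%s)\n", x$reactor_id, pot))
  cat(sprintf("  consumption: %.2f %%  (%.0f umol/L)\n",
              x$consumption_pct, x$consumed_conc))
  cat(sprintf("  CE: %s  r_CAT: %s\n",
              if (is.na(x$ce_pct)) "n/a" else sprintf("%.3f %%", x$ce_pct),
              if (is.na(x$r_cat_pct)) "n/a" else sprintf("%.2f %%", x$r_cat_pct)))
  cat(sprintf("  CCE: %.1f %%  ECE: %.1f %%%s\n", x$cce_total, x$ece_total,
              if (x$overshoot) "  [share sum exceeds 100 %]" else ""))
  invisible(x)
}

#' Tidy a balance report into a long share table
#'
#' @param x A `balance_report`.
#' @param ... Unused.
#' @return A tibble with columns `reactor_id`, `partition` (`"carbon"` or
#'   `"electron"`), `pool` and `share_pct`.
#' @export
tidy.balance_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$carbon, partition = "carbon"),
    dplyr::mutate(x$electron, partition = "electron")
  ) |>
    dplyr::mutate(reactor_id = x$reactor_id) |>
    dplyr::select("reactor_id", "partition", "pool", "share_pct")
}

#' One-row summary of a balance report
#'
#' @param x A `balance_report`.
#' @param ... Unused.
#' @return A one-row tibble with consumption, yields, charges, CE, r_CAT
#'   and the CCE/ECE totals.
#' @export
glance.balance_report <- function(x, ...) {
  cl <- setNames(x$coulombs$coulombs, x$coulombs$pool)
  yl <- setNames(x$yields$yield_mol_mol, x$yields$species)
  tibble::tibble(
    reactor_id = x$reactor_id,
    applied_potential = x$applied_potential,
    consumption_pct = x$consumption_pct,
    consumed_conc_umol_l = x$consumed_conc,
    yield_ethanol = unname(yl["ethanol"]),
    yield_acetate = unname(yl["acetate"]),
    c_ethanol = unname(cl["ethanol"]),
    c_acetate = unname(cl["acetate"]),
    c_h2 = unname(cl["hydrogen"]),
    c_substrate = unname(cl["substrate"]),
    c_i = unname(cl["current"]),
    ce_pct = x$ce_pct,
    r_cat_pct = x$r_cat_pct,
    cce_total = x$cce_total,
    ece_total = x$ece_total,
    overshoot = x$overshoot
  )
}

#' Balance every reactor in a batch table
#'
#' Maps [balance_report()] over a reactor batch table (one row per reactor,
#' as produced by [make_benchmark_fixture()] or [make_reactor_batch()]).
#'
#' @param batches Tibble with the reactor spec and panel columns and an
#'   optional `trace` list-column; see [make_benchmark_fixture()].
#' @return A tibble with one row per reactor (the [glance()] of each
#'   report) and a `report` list-column holding the full objects.
#' @examples
#' balance_all(make_benchmark_fixture())
#' @export
balance_all <- function(batches) {
  stopifnot(is.data.frame(batches), nrow(batches) >= 1)
  pick <- function(row, keys) row[intersect(keys, names(row))]
  reports <- purrr::pmap(batches, function(...) {
    row <- list(...)
    balance_report(
      spec = pick(row, c("reactor_id", "applied_potential", "volume_l",
                         "initial_substrate", "substrate_molar_mass",
                         "duration_h")),
      panel = pick(row, c("consumed_fraction", "substrate_final", "ethanol",
                          "acetate", "hydrogen", "biomass")),
      trace = row$trace,
      c_i = if (is.null(row$c_i) || is.na(row$c_i)) NULL else row$c_i
    )
  })
  out <- purrr::map_dfr(reports, glance)
  out$report <- reports
  out
}
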