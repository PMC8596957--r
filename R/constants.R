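#' Physical constants used throughout the package
#'
#' `faraday_constant()` returns the Faraday constant in C per mol of
#' electrons; `molar_gas_volume()` returns the molar gas volume (L mol^-1)
#' used to convert a hydrogen gas volume to moles at reactor conditions;
#' `xylose_molar_mass()` returns the molar mass of xylose (g mol^-1).
#'
#' @return A single numeric value.
#' @export
faraday_constant <- function() 96485

#' @rdname faraday_constant
#' @export
molar_gas_volume <- function() 24.03

#' @rdname faraday_constant
#' @export
xylose_molar_mass <- function() 150.13

#' Per-species stoichiometric bookkeeping constants
#'
#' The five species tracked by the balance: the substrate (xylose), the
#' fermentation products (ethanol, acetate, hydrogen) and biomass with
#' elemental formula C5H7O2N. Two electron-bookkeeping conventions coexist
#' and are never mixed:
#'
#' * `electron_equiv` — electron equivalents per mole under the full-oxidation
#'   convention (xylose 20, ethanol 12, acetate 8, H2 2, biomass 20), used by
#'   the electron conversion efficiency (ECE) partition.
#' * `coulomb_b` — net electrons transferred per mole of product formed from
#'   0.6 mol xylose via the EMP pathway (ethanol 3.4, acetate 0.6, H2 2;
#'   xylose itself 20), used by the metabolite-coulomb equation
#'   C = F * b * V * dC.
#'
#' @return A tibble with columns `species`, `carbon_atoms`, `electron_equiv`,
#'   `coulomb_b` and `molar_mass` (g mol^-1).
#' @examples
#' species_constants()
#' @export
species_constants <- function() {
  tibble::tibble(
    species        = c("xylose", "ethanol", "acetate", "hydrogen", "biomass"),
    carbon_atoms   = c(5, 2, 2, 0, 5),
    electron_equiv = c(20, 12, 8, 2, 20),
    coulomb_b      = c(20, 3.4, 0.6, 2, NA_real_),
    molar_mass     = c(150.13, 46.07, 60.05, 2.016, 113.11)
  )
}

species_constant <- function(species, field) {
  tab <- species_constants()
  i <- match(species, tab$species)
  if (anyNA(i)) {
    abort(paste0("unknown species: ", paste(species[is.na(i)], collapse = ", ")))
  }
  val <- tab[[field]][i]
  if (anyNA(val)) {
    abort(paste0("species '", paste(species[is.na(val)], collapse = ", "),
                 "' has no '", field, "' entry"))
  }
  val
}
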