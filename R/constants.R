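#' Physical constants and unit conventions
#'
#' The package works in Angstrom / kcal/mol / Kelvin throughout.
#' Kirkwood-Buff integrals are reported both in A^3/molecule and in L/mol.
#'
#' @name kbsolv-units
#' @keywords internal
NULL

## gas constant, kcal mol^-1 K^-1
R_GAS_KCAL <- 1.987204e-3

## A^3 molecule^-1  ->  L mol^-1   (N_A * 1e-27)
A3_PER_MOLECULE_TO_L_PER_MOL <- 6.02214076e-4

#' Convert a molar concentration to a number density
#'
#' @param conc concentration in mol/L.
#' @return number density in molecules per cubic Angstrom.
#' @examples
#' molar_to_density(55.5) # bulk water
#' @export
molar_to_density <- function(conc) {
  conc * A3_PER_MOLECULE_TO_L_PER_MOL
}

#' Convert a number density to a molar concentration
#'
#' @param rho number density in molecules per cubic Angstrom.
#' @return concentration in mol/L.
#' @export
density_to_molar <- function(rho) {
  rho / A3_PER_MOLECULE_TO_L_PER_MOL
}

## Default backbone atom-name set for backbone/side-chain partitioning.
## Glycine HA2/HA3 count as backbone.
BACKBONE_ATOM_NAMES <- c("N", "CA", "C", "O", "H", "HA", "HA2", "HA3", "HN", "OXT")

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so package functions do not perturb user streams.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
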