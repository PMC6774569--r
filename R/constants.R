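#' Physical constants used throughout the package
#'
#' All internal units are nm (length), kcal/mol (energy), e (charge), amu
#' (mass), K (temperature), ps (time). Angstrom appears only at file-format
#' boundaries (PDB, OpenDX) where it is converted by the exact factor 0.1.
#'
#' @name constants
#' @keywords internal
NULL

## Boltzmann constant, kcal/(mol K)
.kB <- 0.0019872041

## Coulomb prefactor, kcal nm / (mol e^2): 332.0636 kcal A/(mol e^2) * 0.1
.kCoulomb <- 33.20636

## Avogadro's number, 1/mol
.NAvogadro <- 6.02214076e23

#' Boltzmann constant in simulation units
#'
#' @return The Boltzmann constant, 0.0019872041 kcal/(mol K).
#' @export
#' @examples
#' boltzmannConstant() * 300  # thermal energy at 300 K, kcal/mol
boltzmannConstant <- function() .kB

#' Standard-state volume per molecule
#'
#' Volume available to one molecule at the standard concentration of 1 M,
#' computed from Avogadro's number: 1 L / N_A expressed in cubic Angstrom.
#' Rounds to the conventional 1661 A^3.
#'
#' @return Standard volume in A^3 (about 1660.54).
#' @export
#' @examples
#' round(standardVolume())  # 1661
standardVolume <- function() {
  1e27 / .NAvogadro
}

## van der Waals radii (nm) for the elements the pipeline meets; coarse
## beads can override via the sidecar parameter table's radius column.
.vdwRadii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, P = 0.180, S = 0.180,
  K = 0.275, NA. = 0.227, CL = 0.175, MG = 0.173, F = 0.147, BR = 0.185
)

## atomic masses (amu); unknown elements get mass 0 with a warning and are
## excluded from centre-of-mass computations
.elementMasses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  K = 39.098, NA. = 22.990, CL = 35.45, MG = 24.305, F = 18.998,
  BR = 79.904
)

.elementMass <- function(element) {
  key <- ifelse(toupper(element) %in% c("NA"), "NA.", toupper(element))
  m <- .elementMasses[key]
  unname(ifelse(is.na(m), 0, m))
}

.elementRadius <- function(element) {
  key <- ifelse(toupper(element) %in% c("NA"), "NA.", toupper(element))
  r <- .vdwRadii[key]
  unname(ifelse(is.na(r), 0.17, r))
}
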