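## Monoisotopic mass constants (Da).  Residue masses are for the free
## (unsubstituted) monosaccharide; substituents and glycosidic condensation
## are applied on top.  All values derive from standard atomic monoisotopic
## masses (H 1.0078250319, C 12, N 14.0030740052, O 15.9949146221,
## S 31.97207069) and are cross-checked against an atom-count oracle in the
## test suite.

.MASS <- list(
  dU     = 176.03209,   # C6H8O6, 4,5-unsaturated uronic acid
  U      = 194.04265,   # C6H10O7, saturated uronic acid (IdoA/GlcA)
  A      = 179.07937,   # C6H13NO5, glucosamine (free amine)
  aMol   = 164.06847,   # C6H12O5, 2,5-anhydromannitol
  Rc     = 164.06847,   # C6H12O5, ring-contracted residue
  SO3    = 79.95682,    # sulfation (+SO3)
  NAc    = 42.01057,    # N-acetylation (+C2H2O)
  H2O    = 18.01056,    # glycosidic condensation / hydrolysis
  proton = 1.007276,
  DBA    = 129.15175,   # dibutylamine C8H19N, neutral ion-pairing adduct
  CO2    = 43.98983
)

## Cross-ring 0,2 cleavage of a glucosamine ring partitions the residue into
## a C1-C2 unit (anomeric oxygen + N-substituent) and a C3-C6 unit (O3, ring
## oxygen, O6); the two base compositions sum exactly to the free residue.
.XRING <- list(
  C1C2 = 59.03711,      # C2H5NO
  C3C6 = 120.04226      # C4H8O4
)

## Auxiliary residues for linkage-region species (xylose-serine stub);
## provided for mass-table completeness only.
.MASS_AUX <- list(
  Gal = 180.06339,      # C6H12O6
  Xyl = 150.05282,      # C5H10O5
  Ser = 105.04259       # C3H7NO3
)

#' Monoisotopic mass constants used by the mass engine
#'
#' Free-residue monoisotopic masses (Da) for the residue classes of the
#' sequence grammar, together with the substituent, water, proton,
#' dibutylamine (DBA) and CO2 masses used throughout m/z arithmetic.
#'
#' @return named list of masses in Da.
#' @examples
#' residueMasses()$SO3
#' @export
residueMasses <- function() .MASS

## per-residue mass including substituents (vectorised over residue rows)
.residueMassVec <- function(r) {
  base <- unlist(.MASS[r$class], use.names = FALSE)
  ns <- !is.na(r$nsub) & r$nsub == "NS"
  nac <- !is.na(r$nsub) & r$nsub == "NAc"
  nsulf <- r$s2 + r$s3 + r$s6 + ns
  base + nsulf * .MASS$SO3 + nac * .MASS$NAc
}

## per-residue sulfate count
.residueSulfVec <- function(r) {
  ns <- !is.na(r$nsub) & r$nsub == "NS"
  as.integer(r$s2 + r$s3 + r$s6 + ns)
}
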