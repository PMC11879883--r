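# Monoisotopic mass model.  Residue masses are the standard 20-residue
# monoisotopic table (Da); water and proton to the precision needed to
# reproduce published 4-decimal precursor m/z values.
.AA_MONO <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202840, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.MASS_WATER    <- 18.0105646863
.MASS_PROTON   <- 1.00727646688   # bare proton, not hydrogen atom
.MASS_PHOSPHO  <- 79.96633        # HPO3 addition, the "[+80]" label
.MASS_H_LOSS   <- -1.0078250319   # loss of one H atom, the "[-1]" label

# Bracket labels with a fixed chemical meaning.  Keys are the label text with
# any Unicode minus normalised to ASCII "-".
.KNOWN_MODS <- c("+80" = .MASS_PHOSPHO, "-1" = .MASS_H_LOSS)

#' Mass constants used by the monoisotopic mass model
#'
#' Returns the immutable constants behind [monoisotopicMass()] and
#' [precursorMz()]: the 20 standard residue monoisotopic masses, the mass of
#' water, the proton mass used in the charge term, and the deltas assigned to
#' the recognised bracket labels (`"+80"` = phospho, `"-1"` = loss of one
#' hydrogen atom, as in an intramolecular disulfide).
#'
#' @return A named list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton`, `phospho`, `hydrogen_loss` (each numeric, Da).
#' @examples
#' massConstants()$water
#' @export
massConstants <- function() {
  list(residues = .AA_MONO, water = .MASS_WATER, proton = .MASS_PROTON,
       phospho = .MASS_PHOSPHO, hydrogen_loss = .MASS_H_LOSS)
}
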