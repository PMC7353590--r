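# Monoisotopic mass bookkeeping. Residue and constituent masses are the
# standard monoisotopic values at full precision (8 dp; 6-dp tables can
# flip the 4th decimal of high-DP PEG fragments once multiplied out);
# charging uses the proton mass, not the hydrogen atom mass.

.RESIDUE_MASSES <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496300, E = 129.04259308, M = 131.04048459, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294)

.PROTON_MASS <- 1.00727646688
.WATER_MASS <- 18.01056468
.ETHYLENE_OXIDE_MASS <- 44.02621475

.MODIFICATIONS <- c(
  carbamidomethyl   = 57.02146372,
  oxidation         = 15.99491462,
  phosphorylation   = 79.96633089,
  acetylation       = 42.01056468,
  label_13C6_15N2_K = 8.01419898)

#' Monoisotopic mass constants
#'
#' The mass scale used throughout the package: monoisotopic residue masses
#' for the 20 standard amino acids, the proton, water and ethylene-oxide
#' unit masses, and the named modification deltas (including the
#' 13C6,15N2 lysine label of the SIS peptide).
#'
#' @return A list with elements \code{residue_masses} (named numeric, 20
#'   residues), \code{proton_mass}, \code{water_mass},
#'   \code{ethylene_oxide_mass} (Da), and \code{modifications} (named
#'   numeric deltas in Da).
#' @examples
#' massConstants()$residue_masses[["K"]]
#' massConstants()$modifications[["label_13C6_15N2_K"]]
#' @export
massConstants <- function() {
  list(residue_masses = .RESIDUE_MASSES,
       proton_mass = .PROTON_MASS,
       water_mass = .WATER_MASS,
       ethylene_oxide_mass = .ETHYLENE_OXIDE_MASS,
       modifications = .MODIFICATIONS)
}

# residue-mass lookup with a diagnostic naming the offending token
.residueMasses <- function(residues) {
  bad <- setdiff(residues, names(.RESIDUE_MASSES))
  if (length(bad))
    stop(sprintf("unknown residue(s): %s", paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  .RESIDUE_MASSES[residues]
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param p A \code{\linkS4class{ModifiedPeptide}}.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptideMass(modifiedPeptide("LLIYDTSK"))  # 951.5277 Da
#' @export
peptideMass <- function(p) {
  stopifnot(is(p, "ModifiedPeptide"))
  validObject(p)
  residues <- strsplit(p@sequence, "")[[1L]]
  mass <- sum(.residueMasses(residues)) + .WATER_MASS
  if (nrow(p@modifications))
    mass <- mass + sum(.MODIFICATIONS[p@modifications$name])
  mass
}

#' Precursor m/z of a peptide
#'
#' \code{(monoisotopic mass + charge * proton) / charge} at the peptide's
#' charge state.
#'
#' @param p A \code{\linkS4class{ModifiedPeptide}} with charge >= 1.
#' @return Precursor m/z.
#' @examples
#' precursorMz(modifiedPeptide("LLIYDTSK", charge = 2))  # 476.7711
#' @export
precursorMz <- function(p) {
  stopifnot(is(p, "ModifiedPeptide"))
  validObject(p)
  (peptideMass(p) + p@charge * .PROTON_MASS) / p@charge
}

#' y-ion m/z of a peptide
#'
#' m/z of the C-terminal \code{k}-residue fragment (the y-ion series, the
#' dominant series under HCD for tryptic peptides). Modifications attach to
#' the fragment iff their residue lies within the C-terminal \code{k}
#' residues, so an isotope label on the C-terminal lysine shifts every
#' y-ion by its full delta.
#'
#' @param p A \code{\linkS4class{ModifiedPeptide}}.
#' @param k Fragment length, \code{1 <= k <= nchar(sequence)}.
#' @param fragmentCharge Fragment charge state (default 1; published
#'   transition tables report \code{[M+H]+}).
#' @return Fragment m/z.
#' @examples
#' p <- modifiedPeptide("LLIYDTSK", charge = 2)
#' yIonMz(p, 2)  # 234.1448
#' yIonMz(p, 7)  # 839.4509
#' @export
yIonMz <- function(p, k, fragmentCharge = 1L) {
  stopifnot(is(p, "ModifiedPeptide"))
  validObject(p)
  n <- nchar(p@sequence)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop(sprintf("fragment length k = %d outside 1..%d", k, n), call. = FALSE)
  fragmentCharge <- as.integer(fragmentCharge)
  if (fragmentCharge < 1L)
    stop("'fragmentCharge' must be >= 1", call. = FALSE)
  residues <- strsplit(p@sequence, "")[[1L]]
  frag <- residues[(n - k + 1L):n]
  mass <- sum(.residueMasses(frag)) + .WATER_MASS
  mods <- p@modifications
  if (nrow(mods)) {
    inFrag <- mods$position > n - k
    if (any(inFrag)) mass <- mass + sum(.MODIFICATIONS[mods$name[inFrag]])
  }
  (mass + fragmentCharge * .PROTON_MASS) / fragmentCharge
}

#' m/z of a PEG oligomer or fragment
#'
#' Intact PEG chains and their CID fragments share the same formula: a
#' chain of \code{nUnits} ethylene-oxide repeats plus water, protonated at
#' the given charge:
#' \code{(nUnits * 44.026215 + 18.010565 + charge * 1.007276) / charge}.
#'
#' @param o A \code{\linkS4class{PegOligomer}}.
#' @return m/z.
#' @examples
#' pegMz(pegOligomer(28, charge = 3))  # 417.922 (intact marker)
#' pegMz(pegOligomer(7))               # 327.2013 (DP 7 fragment)
#' @export
pegMz <- function(o) {
  stopifnot(is(o, "PegOligomer"))
  validObject(o)
  (o@nUnits * .ETHYLENE_OXIDE_MASS + .WATER_MASS +
     o@charge * .PROTON_MASS) / o@charge
}

#' Round half-up at a fixed number of decimals
#'
#' Reporting convention for m/z values: half-up rounding (0.00005 rounds
#' up), matching how transition tables are printed -- 4 decimals for
#' singly/doubly charged species, 3 for the triply charged PEG precursor.
#' Base \code{round()} rounds half-to-even, which differs on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return \code{x} rounded half-up to \code{digits} decimals.
#' @examples
#' roundHalfUp(234.14485, 4)  # 234.1449
#' @export
roundHalfUp <- function(x, digits = 4L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}
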