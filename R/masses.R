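# Monoisotopic residue masses (Th) and mass constants used throughout.
# Values are the standard IUPAC monoisotopic amino-acid residue masses.

.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

.PROTON <- 1.00727646688
.WATER <- 18.0105646863
.ISOTOPE_SPACING <- 1.003355      # average C13-C12 spacing, Th
.MOD_CARBAMIDOMETHYL <- 57.021464 # fixed on C
.MOD_OXIDATION <- 15.994915       # variable on M
.MOD_ACETYL <- 42.010565          # variable, protein N-terminus

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide from the standard residue mass
#' table, plus one water, plus any modification mass offset.
#'
#' @param sequence amino-acid string (standard 20 residues).
#' @param modMass total modification mass to add (Th), e.g. one
#'   carbamidomethyl = 57.021464 per cysteine.
#' @return neutral mass in Th, or `NA` if the sequence contains a
#'   non-standard residue.
#' @export
peptideMass <- function(sequence, modMass = 0) {
  aa <- strsplit(sequence, "")[[1]]
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m)) return(NA_real_)
  sum(m) + .WATER + modMass
}

#' Peptide precursor m/z
#'
#' @inheritParams peptideMass
#' @param charge precursor charge state (>= 1).
#' @return (M + z * proton) / z in Th.
#' @export
peptideMz <- function(sequence, charge, modMass = 0) {
  (peptideMass(sequence, modMass) + charge * .PROTON) / charge
}

#' Singly charged b/y fragment ions of a peptide
#'
#' Computes the m/z of all singly protonated b and y ions. Residue
#' modifications are passed as a per-position mass vector so fixed
#' carbamidomethyl and variable oxidation land on the correct fragments;
#' an N-terminal modification (acetyl) is added to every b ion and to the
#' full-length y ion ladder position it belongs to.
#'
#' @param sequence amino-acid string.
#' @param residueMods numeric vector of per-residue modification masses
#'   (length == nchar(sequence)), default all zero.
#' @param ntermMod N-terminal modification mass (added to b ions).
#' @return data.frame with columns `type` ("b"/"y"), `pos`, `mz`, sorted by mz.
#' @export
fragmentIons <- function(sequence, residueMods = NULL, ntermMod = 0) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m)) stop("non-standard residue in ", sequence)
  if (is.null(residueMods)) residueMods <- numeric(n)
  m <- m + residueMods
  cm <- cumsum(m)
  # b_i = sum(res 1..i) + nterm + proton ; y_i = sum(res n-i+1..n) + water + proton
  b <- cm[-n] + ntermMod + .PROTON
  y <- (cm[n] - cm[seq_len(n - 1L)]) + .WATER + .PROTON
  # y as computed runs y_{n-1}..y_1; reverse so pos runs 1..n-1
  out <- data.frame(
    type = c(rep("b", n - 1L), rep("y", n - 1L)),
    pos = c(seq_len(n - 1L), seq_len(n - 1L)),
    mz = c(b, rev(y))
  )
  out[order(out$mz), , drop = FALSE]
}
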