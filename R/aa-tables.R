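## Residue mass tables and modification deltas.
##
## Residue masses are the standard values for the 20 proteinogenic amino acids
## as peptide-bond residues (free amino acid minus one water). Monoisotopic
## values use the most abundant isotope of each element; average values use
## IUPAC standard atomic weights (the convention ProtParam follows).

.AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AA_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG  <- 18.01528

## Mass corrections, in Da, applied on top of the residue sum. Signs follow
## the chemistry: amidation swaps the C-terminal OH for NH2, each disulfide
## bond removes two hydrogens, oxidation adds one oxygen, and so on.
.MOD_DELTAS <- data.frame(
  name = c("amidation", "oxidation", "dehydration", "deamidation",
           "co_loss", "carbamidomethyl", "disulfide"),
  delta_mono = c(-0.98402, 15.99491, -18.01056, 0.98402,
                 -27.99491, 57.02146, -2.01565),
  delta_average = c(-0.9847, 15.9994, -18.0153, 0.9847,
                    -28.0101, 57.0513, -2.0159),
  stringsAsFactors = FALSE
)

#' Residue mass table for the 20 standard amino acids
#'
#' Monoisotopic and average residue masses (free amino acid minus one water),
#' together with the mass of water, which is added back once per peptide.
#' Monoisotopic mass is strictly smaller than average mass for every residue.
#'
#' @return A data frame with columns `residue`, `monoisotopic` and `average`
#'   (Da), carrying the water masses as attributes `water_monoisotopic` and
#'   `water_average`.
#' @examples
#' amino_acid_masses()
#' @export
amino_acid_masses <- function() {
  out <- data.frame(
    residue = names(.AA_MONO),
    monoisotopic = unname(.AA_MONO),
    average = unname(.AA_AVG),
    stringsAsFactors = FALSE
  )
  attr(out, "water_monoisotopic") <- .WATER_MONO
  attr(out, "water_average") <- .WATER_AVG
  out
}

#' Mass deltas for supported covalent modifications
#'
#' C-terminal amidation, methionine/other oxidation, dehydration, deamidation,
#' neutral loss of carbon monoxide, carbamidomethylation of cysteine, and one
#' disulfide bond (loss of two hydrogens).
#'
#' @return A data frame with columns `name`, `delta_mono`, `delta_average`
#'   (Da, signed).
#' @export
modification_deltas <- function() .MOD_DELTAS

.mod_delta <- function(name, kind) {
  row <- .MOD_DELTAS[.MOD_DELTAS$name == name, ]
  if (kind == "mono") row$delta_mono else row$delta_average
}

#' Fauchere-Pliska hydrophobicity scale
#'
#' The octanol/water partition scale of Fauchere and Pliska (1983), the
#' default scale used by HeliQuest for helical-wheel descriptors.
#'
#' @return Named numeric vector over the 20 standard residue letters.
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
    Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
    L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
    S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)
}

## Validate a peptide string against the 20-letter alphabet; returns the
## vector of residues. Ambiguity codes (B/Z/X) and rare letters (U/O) are
## rejected outright: no averaging over ambiguous compositions.
.check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(sprintf("`%s` must be a single non-empty string", arg), call. = FALSE)
  }
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!residues %in% names(.AA_MONO))
  if (length(bad) > 0L) {
    stop(sprintf(
      "`%s` contains non-standard letter '%s' at position %d",
      arg, residues[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  residues
}

## Round half away from zero (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
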