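# Global (whole-peptide) physicochemical descriptors.
#
# Eight classical protein-parameter quantities computed from published
# per-residue scales (see R/scales-data.R): average molecular weight,
# aromaticity, instability index, isoelectric point, GRAVY, and the fractions
# of residues with helix, turn, and sheet propensity. Definitions follow the
# classical ProtParam formulations so values are comparable across tools.

GLOBAL_DESCRIPTOR_NAMES <- c(
  "mol_weight", "aromaticity", "instability", "isoelectric_point",
  "gravy", "helix_frac", "turn_frac", "sheet_frac"
)

peptide_mol_weight <- function(residues) {
  sum(RESIDUE_MASS_AVG[residues]) - (length(residues) - 1) * WATER_MASS_AVG
}

peptide_aromaticity <- function(residues) {
  mean(residues %in% c("F", "W", "Y"))
}

# Guruprasad et al. (1990): II = (10 / L) * sum of dipeptide weights.
peptide_instability <- function(residues) {
  L <- length(residues)
  idx <- cbind(residues[-L], residues[-1])
  10 / L * sum(DIWV[idx])
}

# Net charge at a given pH under the Bjellqvist pKa model, with
# residue-specific terminal pKa adjustments.
peptide_charge_at_ph <- function(residues, ph) {
  pos <- PKA_POSITIVE
  neg <- PKA_NEGATIVE
  first <- residues[1]
  last <- residues[length(residues)]
  if (first %in% names(PKA_NTERM_RESIDUE)) pos[["Nterm"]] <- PKA_NTERM_RESIDUE[[first]]
  if (last %in% names(PKA_CTERM_RESIDUE)) neg[["Cterm"]] <- PKA_CTERM_RESIDUE[[last]]
  counts <- table(factor(residues, levels = AA_CANONICAL))
  n_pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  n_neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  positive <- sum(n_pos / (1 + 10^(ph - pos[c("Nterm", "K", "R", "H")])))
  negative <- sum(n_neg / (1 + 10^(neg[c("Cterm", "D", "E", "C", "Y")] - ph)))
  positive - negative
}

# pI: the charge is strictly decreasing in pH, so bisection via uniroot.
peptide_isoelectric_point <- function(residues) {
  stats::uniroot(
    function(ph) peptide_charge_at_ph(residues, ph),
    interval = c(0, 14), tol = 1e-6
  )$root
}

peptide_gravy <- function(residues) {
  mean(KYTE_DOOLITTLE[residues])
}

#' Global physicochemical descriptors of a peptide
#'
#' Computes the eight peptide-level features appended to the positional
#' encoding, in fixed order: average molecular weight (Da), aromaticity
#' (fraction of F/W/Y), instability index, isoelectric point, GRAVY
#' (mean Kyte-Doolittle hydropathy), and the fractions of residues with
#' helix (E/M/A/L/K), turn (N/P/G/S/D) and sheet (V/I/Y/F/W/L/T) propensity.
#'
#' @param peptide a single peptide sequence using the 20 standard letters.
#' @param lengths allowed peptide lengths; defaults to 9-11.
#' @return a named numeric vector of length 8.
#' @export
#' @examples
#' global_descriptors("AAAAAAAAA")[["gravy"]] # 1.8
global_descriptors <- function(peptide, lengths = 9:11) {
  peptide <- validate_peptides(peptide, lengths = lengths)
  if (length(peptide) != 1) stop("global_descriptors takes one peptide", call. = FALSE)
  r <- strsplit(peptide, "")[[1]]
  out <- c(
    peptide_mol_weight(r),
    peptide_aromaticity(r),
    peptide_instability(r),
    peptide_isoelectric_point(r),
    peptide_gravy(r),
    mean(r %in% SS_HELIX_SET),
    mean(r %in% SS_TURN_SET),
    mean(r %in% SS_SHEET_SET)
  )
  names(out) <- GLOBAL_DESCRIPTOR_NAMES
  out
}
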