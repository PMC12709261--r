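# Reference data shared across modules: peptide sequences, residue/atom
# chemistry tables, and radii.

#' Built-in peptide sequences
#'
#' One-letter sequences for the three peptides the package's analyses were
#' designed around: the 42-residue amyloid-beta isoform, the 31-residue
#' beta-endorphin isoform, and the C-terminal amyloid-beta mutant
#' (I31K/I32N, V36K/G37N) that disrupts the hydrophobic C-terminus.
#'
#' @format Named character vector of one-letter sequences.
#' @export
amyloid_sequences <- c(
  abeta42     = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA",
  bend31      = "YGGFMTSEKSQTPLVTLFKNAIIKNAYKKGE",
  abeta42_mut = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAKNGLMKNGVVIA"
)

# one-letter -> three-letter residue codes
.aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Default hydrophobic residue set
#'
#' Residues counted towards hydrophobic solvent-accessible surface area.
#' @export
hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "TRP")

# Bondi van der Waals radii (nm) by element; fallback handled at lookup
.bondi_radii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
  P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198
)

.default_vdw_radius <- 0.170

# atomic masses (u) for mass-weighted descriptors when elements are known
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

.vdw_radius_for_element <- function(element) {
  r <- unname(.bondi_radii[toupper(element)])
  miss <- is.na(r)
  if (any(miss)) {
    warn(sprintf(
      "Unknown element(s) %s: assigning fallback vdW radius %.2f nm",
      paste(unique(element[miss]), collapse = ", "), .default_vdw_radius
    ))
    r[miss] <- .default_vdw_radius
  }
  r
}

# Guess the element from a PDB/GRO atom name (first alphabetic character,
# skipping leading digits; "1HB" -> H, "CA" -> C).
.element_from_atom_name <- function(atom_name) {
  nm <- toupper(gsub("^[0-9 ]+", "", atom_name))
  substr(nm, 1L, 1L)
}

#' Expand a one-letter sequence to three-letter residue names
#'
#' @param sequence One-letter amino-acid string.
#' @return Character vector of three-letter codes.
#' @export
sequence_to_residues <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  out <- unname(.aa_three[letters1])
  if (anyNA(out)) {
    abort(sprintf(
      "Unknown one-letter residue code(s): %s",
      paste(unique(letters1[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

# default sequence for a synthetic chain of a given length
.default_sequence <- function(n_residues) {
  if (n_residues == 42L) return(amyloid_sequences[["abeta42"]])
  if (n_residues == 31L) return(amyloid_sequences[["bend31"]])
  base <- "GAVLIFPSTYEDKRNQHMWC"
  paste(strsplit(base, "")[[1]][(seq_len(n_residues) - 1L) %% nchar(base) + 1L],
        collapse = "")
}
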