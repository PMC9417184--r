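# Amino-acid lookup tables used across the package. All masses are average
# (isotope-abundance weighted) residue masses in Da, i.e. the free amino acid
# minus one water; electron counts are for the neutral residue within a chain.

#' @keywords internal
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

#' @keywords internal
aa_one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# IUPAC average residue masses (Da); water = 18.0153 Da per chain terminus pair.
#' @keywords internal
aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' @keywords internal
water_mass <- 18.0153

# Electron counts of neutral in-chain residues (formula minus water).
#' @keywords internal
aa_residue_electrons <- c(
  G = 30, A = 38, S = 46, P = 52, V = 54, T = 54, C = 54,
  L = 62, I = 62, N = 60, D = 60, Q = 68, K = 70, E = 68,
  M = 70, H = 72, F = 78, R = 84, Y = 86, W = 98
)

#' @keywords internal
element_electrons <- c(H = 1, C = 6, N = 7, O = 8, S = 16, SE = 34, P = 15)

#' @keywords internal
backbone_atom_names <- c("N", "CA", "C", "O", "OXT")

# Side-chain hydrogen-bond donor / acceptor heavy atoms, by residue type.
# Classification is distance-only (no hydrogens, no angular term); backbone N
# is always donor-capable and backbone O/OXT always acceptor-capable.
#' @keywords internal
sidechain_donors <- list(
  R = c("NE", "NH1", "NH2"), K = "NZ", H = c("ND1", "NE2"),
  N = "ND2", Q = "NE2", S = "OG", T = "OG1", Y = "OH", W = "NE1"
)

#' @keywords internal
sidechain_acceptors <- list(
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  H = c("ND1", "NE2"), S = "OG", T = "OG1", Y = "OH"
)

# Charged-group heavy atoms for salt-bridge detection.
#' @keywords internal
basic_atoms <- list(R = c("NH1", "NH2", "NE"), K = "NZ", H = c("ND1", "NE2"))

#' @keywords internal
acidic_atoms <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"))

# Residue classes used when a side chain is represented by a single "SC"
# pseudo-atom (coarse models): the pseudo-atom inherits the polar capability
# of the side chain it stands for.
#' @keywords internal
sc_donor_residues <- c("R", "K", "H", "N", "Q", "S", "T", "Y", "W")
#' @keywords internal
sc_acceptor_residues <- c("D", "E", "N", "Q", "H", "S", "T", "Y")
#' @keywords internal
sc_basic_residues <- c("R", "K", "H")
#' @keywords internal
sc_acidic_residues <- c("D", "E")

# Distance (Angstrom) from CA to the side-chain centroid of an idealized
# extended side chain; used to place "SC" pseudo-atoms in coarse models.
#' @keywords internal
sc_centroid_distance <- c(
  G = 0,    A = 1.53, S = 1.9,  C = 2.1,  P = 1.9,  T = 1.9,  V = 2.0,
  L = 2.6,  I = 2.4,  N = 2.5,  D = 2.5,  Q = 3.1,  E = 3.1,  M = 2.9,
  H = 3.1,  K = 3.5,  F = 3.4,  R = 4.1,  Y = 3.8,  W = 3.9
)

#' @keywords internal
aa_one_letter <- function(resname) {
  out <- unname(aa_three_to_one[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}
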