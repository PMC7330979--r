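# Amino-acid lookup tables shared across modules.
#
# The interaction atom lists and cutoffs are implemented verbatim, including
# the surprising entries (LYS NZ appears under hydrogen bonds but not ionic;
# HIS lists ring carbons under ionic).  Changing them would silently change
# database contents, so fidelity wins over chemical second-guessing.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Residue types that can seed a database entry: the 11 hydrogen-bond/ionic
# capable side chains, plus cysteine (disulfide bonds only).
DB_RESIDUES_HB <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS",
                    "SER", "THR", "TRP", "TYR")
DB_RESIDUES <- c(DB_RESIDUES_HB, "CYS")

# Side-chain atoms allowed to form each interaction kind, with distance
# cutoffs (heavy atoms, Angstrom).  Hydrogen bond < 3.50; ionic < 6.00
# between one positive-group and one negative-group atom; disulfide
# SG-SG < 2.08.
HB_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  ASN = c("ND2", "OD1"),
  ASP = c("OD1", "OD2"),
  GLN = c("NE2", "OE1"),
  LYS = c("NZ"),
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  SER = c("OG"),
  THR = c("OG1"),
  TRP = c("NE1"),
  TYR = c("OH")
)

IONIC_POSITIVE_ATOMS <- list(
  ARG = c("CZ"),
  HIS = c("CD2", "CE1", "CG")
)

IONIC_NEGATIVE_ATOMS <- list(
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD")
)

DISULFIDE_ATOMS <- list(CYS = c("SG"))

INTERACTION_CUTOFFS <- c(hydrogen_bond = 3.50, ionic = 6.00,
                         disulfide = 2.08)

# ---- Contact-classification tables (seven evaluation contact types) ----

# Side-chain hydrogen-bond donors / acceptors plus the backbone amide N
# (donor) and carbonyl O (acceptor).  Cleaned structures carry no hydrogens,
# so donor capability is a property of the heavy atom.
DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = c("ND2"), GLN = c("NE2"),
  HIS = c("ND1", "NE2"), LYS = c("NZ"), SER = c("OG"), THR = c("OG1"),
  TRP = c("NE1"), TYR = c("OH"), CYS = c("SG")
)

ACCEPTOR_ATOMS <- list(
  ASN = c("OD1"), ASP = c("OD1", "OD2"), GLN = c("OE1"),
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = c("OG"),
  THR = c("OG1"), TYR = c("OH"), MET = c("SD")
)

# Formal-charge groups for the evaluation-side ionic contact (<= 4.0 A).
CHARGE_POSITIVE_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2")
)
CHARGE_NEGATIVE_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# Apolar atoms: side-chain carbons not bonded to N/O/S, plus sulfur in MET.
APOLAR_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG"),
  ASN = c("CB"),
  ASP = c("CB"),
  CYS = c("CB"),
  GLN = c("CB", "CG"),
  GLU = c("CB", "CG"),
  HIS = c("CB"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"),
  THR = c("CG2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2")
)

# Aromatic rings (heavy atoms); TRP contributes both its five- and
# six-membered rings.  Centroid = mean of ring atoms.
AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

CONTACT_TYPES <- c("hydrogen_bond", "weak_hb", "ionic", "aromatic",
                   "polar", "weak_polar", "hydrophobic")

# Property classes used by the proposal category filters.
CATEGORY_POSITIVE <- c("ARG", "LYS", "HIS")
CATEGORY_NEGATIVE <- c("ASP", "GLU")
CATEGORY_AROMATIC <- c("TRP", "TYR", "HIS")
CATEGORY_HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE")

# ---- Pharmacophore classes for cutoff-scanning signatures ----

PHARMACOPHORE_CLASSES <- c("hydrophobic", "aromatic", "positive", "negative",
                           "donor", "acceptor", "sulfur", "neutral")

#' Pharmacophore classes of one atom
#'
#' Atoms may belong to several classes (e.g. HIS NE2 is positive, donor and
#' acceptor); atoms matching no class are typed neutral.
#'
#' @param resname three-letter residue code
#' @param atom PDB atom name
#' @return character vector of class names (subset of
#'   `PHARMACOPHORE_CLASSES`)
#' @keywords internal
atom_pharmacophore <- function(resname, atom) {
  cls <- character(0)
  in_tab <- function(tab) atom %in% tab[[resname]]
  if (in_tab(APOLAR_ATOMS)) cls <- c(cls, "hydrophobic")
  rings <- AROMATIC_RINGS[[resname]]
  if (!is.null(rings) && atom %in% unlist(rings)) cls <- c(cls, "aromatic")
  if (in_tab(CHARGE_POSITIVE_ATOMS)) cls <- c(cls, "positive")
  if (in_tab(CHARGE_NEGATIVE_ATOMS)) cls <- c(cls, "negative")
  if (atom == "N" || in_tab(DONOR_ATOMS)) cls <- c(cls, "donor")
  if (atom %in% c("O", "OXT") || in_tab(ACCEPTOR_ATOMS))
    cls <- c(cls, "acceptor")
  if (substr(atom, 1, 1) == "S") cls <- c(cls, "sulfur")
  if (length(cls) == 0) cls <- "neutral"
  unique(cls)
}
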