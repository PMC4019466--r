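#' @keywords internal
#' @importFrom stats coef lm lm.fit approx rnorm runif
#' @importFrom utils read.csv read.table write.table data packageVersion
"_PACKAGE"

## Chemical dictionaries shared across modules.  All tables use upper-case
## PDB-style atom and residue names.

# Bondi-type van der Waals radii (Angstrom).  Unknown elements fall back to
# 1.80 A; crystal structures analysed here carry no hydrogens, but H is
# listed for completeness.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  MG = 1.73, ZN = 1.39, FE = 1.80, MN = 1.80, CA = 1.80, "NA" = 2.27, K = 2.75
)
.vdw_default <- 1.80

.aa3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

.nuc_names <- c("A", "U", "G", "C", "I",
                "DA", "DT", "DG", "DC", "DI")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Classify a residue name as protein, nucleic or other
#' @param resid character vector of residue names
#' @return character vector in {"protein","nucleic","other"}
#' @keywords internal
.residue_kind <- function(resid) {
  resid <- toupper(resid)
  out <- rep("other", length(resid))
  out[resid %in% names(.aa3)] <- "protein"
  out[resid %in% .nuc_names] <- "nucleic"
  out
}

#' One-letter code for residue names
#' @keywords internal
.residue_letter <- function(resid) {
  resid <- toupper(resid)
  kind <- .residue_kind(resid)
  out <- ifelse(kind == "protein", unname(.aa3[resid]), NA_character_)
  nuc <- kind == "nucleic"
  out[nuc] <- sub("^D", "", resid[nuc])
  out[kind == "protein" & is.na(out)] <- "X"
  out[nuc & !out %in% c("A", "C", "G", "T", "U", "I")] <- "N"
  out
}

.element_from_name <- function(elety, resid) {
  # PDB element inference when the element column is absent: first letter of
  # the stripped atom name, honouring two-letter ions is not needed for the
  # polymer atoms handled here.
  e <- sub("^[0-9']*", "", toupper(elety))
  substr(e, 1, 1)
}

# Heavy-atom hydrogen-bond capability per residue type.  Backbone N is a
# donor, backbone O an acceptor for every amino acid; nucleotides donate and
# accept through base/ribose N and O atoms, and accept on phosphate oxygens.
.hb_donors <- list(
  backbone_protein = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG"
)
.hb_acceptors <- list(
  backbone_protein = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)
# nucleic acids: treat every base/sugar N and O as donor-or-acceptor capable
# and phosphate oxygens as acceptors; with no hydrogens in the model a
# distance-only criterion cannot distinguish donor from acceptor anyway.
.phosphate_oxygens <- c("OP1", "OP2", "OP3", "O1P", "O2P", "O3P")

.basic_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
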