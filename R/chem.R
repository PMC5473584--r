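# Residue-name classification and single-letter codes used when the input
# carries no entity information (PDB files) and for the reduced profile.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

.NUC <- c(A = "A", C = "C", G = "G", U = "U", DA = "A", DC = "C", DG = "G",
          DT = "T", DU = "U", I = "I", DI = "I")

.WATER <- c("HOH", "WAT", "DOD")

# One of "polypeptide", "polynucleotide", "water", "non-polymer".
classify_group <- function(group_name) {
  ifelse(group_name %in% names(.AA3), "polypeptide",
    ifelse(group_name %in% names(.NUC), "polynucleotide",
      ifelse(group_name %in% .WATER, "water", "non-polymer")))
}

single_letter_code <- function(group_name) {
  out <- .AA3[group_name]
  out[is.na(out)] <- .NUC[group_name[is.na(out)]]
  out[is.na(out)] <- "?"
  unname(out)
}

chem_comp_type_for <- function(group_name) {
  cls <- classify_group(group_name)
  c(polypeptide = "L-PEPTIDE LINKING",
    polynucleotide = "RNA LINKING",
    water = "NON-POLYMER",
    `non-polymer` = "NON-POLYMER")[cls]
}

.BOND_ORDER_WORDS <- c(SING = 1, DOUB = 2, TRIP = 3, QUAD = 4)
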