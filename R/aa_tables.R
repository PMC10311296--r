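# Reference tables for the 20 standard amino acids.

#' Heavy-atom topology of the 20 standard amino acids
#'
#' For each 3-letter residue code, the PDB names of its heavy atoms in a
#' fixed order: backbone N, CA, C, O first, then the side-chain atoms in
#' standard topology order (outward from CB). Terminal OXT and all hydrogens
#' are excluded. Summed over the 20 residues this enumeration contains
#' exactly 167 (residue, atom) pairs, which is what the full one-hot channel
#' scheme encodes.
#'
#' @return Named list of character vectors, names are 3-letter codes in
#'   alphabetical order.
#' @export
#' @examples
#' length(unlist(residue_topology()))  # 167
residue_topology <- function() {
  bb <- c("N", "CA", "C", "O")
  list(
    ALA = c(bb, "CB"),
    ARG = c(bb, "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c(bb, "CB", "CG", "OD1", "ND2"),
    ASP = c(bb, "CB", "CG", "OD1", "OD2"),
    CYS = c(bb, "CB", "SG"),
    GLN = c(bb, "CB", "CG", "CD", "OE1", "NE2"),
    GLU = c(bb, "CB", "CG", "CD", "OE1", "OE2"),
    GLY = bb,
    HIS = c(bb, "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c(bb, "CB", "CG1", "CG2", "CD1"),
    LEU = c(bb, "CB", "CG", "CD1", "CD2"),
    LYS = c(bb, "CB", "CG", "CD", "CE", "NZ"),
    MET = c(bb, "CB", "CG", "SD", "CE"),
    PHE = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c(bb, "CB", "CG", "CD"),
    SER = c(bb, "CB", "OG"),
    THR = c(bb, "CB", "OG1", "CG2"),
    TRP = c(bb, "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
            "CZ2", "CZ3", "CH2"),
    TYR = c(bb, "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c(bb, "CB", "CG1", "CG2")
  )
}

#' Standard amino-acid code conversions
#'
#' @return Named character vector mapping 3-letter to 1-letter codes.
#' @export
aa_three_to_one <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
}

#' @rdname aa_three_to_one
#' @return `aa_one_to_three()`: the inverse mapping.
#' @export
aa_one_to_three <- function() {
  x <- aa_three_to_one()
  stats::setNames(names(x), unname(x))
}

# Element symbol of a heavy atom from its PDB atom name (first letter of the
# stripped name: works for all standard heavy atoms, whose names start with
# the element).
element_from_name <- function(atom_name) {
  substr(trimws(atom_name), 1L, 1L)
}

#' Maximal residue solvent accessibility reference (Tien et al. 2013,
#' theoretical values, A^2)
#'
#' Used to convert absolute ASA into relative ASA (rASA = ASA / maxASA).
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
max_asa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Mean residue volumes (Zamyatnin 1972, A^3)
#'
#' Used to classify the size change of a substitution (size-neutral,
#' small-to-large, large-to-small with a 10 A^3 threshold).
#'
#' @return Named numeric vector keyed by 1-letter residue code.
#' @export
residue_volume_reference <- function() {
  c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
}

#' Interface physicochemical propensity table
#'
#' Per-residue propensity to occur at protein-protein interfaces relative to
#' the remaining surface (log-odds style scale; positive = enriched at
#' interfaces). The bundled values are interface enrichment propensities in
#' the spirit of classical interface composition analyses
#' (Jones & Thornton-type statistics); any user table with the same shape
#' (named numeric vector, 1-letter codes) can be supplied wherever a `pc`
#' argument is accepted.
#'
#' @return Named numeric vector keyed by 1-letter residue code.
#' @export
interface_propensity_reference <- function() {
  c(A = -0.17, R = 0.27, N = 0.12, D = -0.38, C = 0.43,
    Q = -0.11, E = -0.13, G = -0.07, H = 0.41, I = 0.44,
    L = 0.40, K = -0.36, M = 0.66, F = 0.82, P = -0.25,
    S = -0.33, T = -0.18, W = 0.83, Y = 0.66, V = 0.27)
}

# Van der Waals radii (A) for the four heavy elements, Bondi-style.
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
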