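# PDB reading/writing and the two-partner structure container.

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Residue key
#'
#' Canonical string identifying a residue: `chain|resno|insert`.
#'
#' @param chain Chain id(s).
#' @param resno Author residue number(s).
#' @param insert Insertion code(s); `NA` or `""` for none.
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = "|")
}

new_ppi_structure <- function(atoms, partner1, partner2) {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms,
                 partner1 = sort(unique(partner1)),
                 partner2 = sort(unique(partner2))),
            class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat(sprintf("<ppi_structure> %d atoms, %d residues; partners [%s] vs [%s]\n",
              nrow(x$atoms),
              length(unique(residue_key(x$atoms$chain, x$atoms$resno,
                                        x$atoms$insert))),
              paste(x$partner1, collapse = ","),
              paste(x$partner2, collapse = ",")))
  invisible(x)
}

#' Read a two-partner protein complex from a PDB file
#'
#' Loads heavy atoms of the standard amino acids from model 1 of a PDB file
#' and splits the chains into the two binding partners. Hydrogens,
#' waters and non-standard hetero groups are dropped; for alternate
#' locations the highest-occupancy conformer is kept (ties broken by altloc
#' id); selenomethionine (MSE) is mapped to MET. A non-standard residue in
#' an ATOM record raises an error.
#'
#' @param path PDB file path.
#' @param partner1,partner2 Character vectors of chain ids forming the two
#'   sides of the interface. Must be disjoint, non-empty and present in the
#'   file.
#' @return A `ppi_structure`: atom table (`chain`, `resno`, `insert`,
#'   `resid`, `elety`, `elesy`, `x`, `y`, `z`, `partner`) plus the partner
#'   chain sets.
#' @export
parse_pdb <- function(path, partner1, partner2) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (length(partner1) < 1 || length(partner2) < 1)
    stop("both partner chain sets must be non-empty")
  if (length(intersect(partner1, partner2)) > 0)
    stop("partner chain sets overlap: ",
         paste(intersect(partner1, partner2), collapse = ","))

  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom

  # model 1 only: bio3d returns the first model's atom table when multi=FALSE
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # map selenomethionine, then drop waters and any other hetero compound
  sel_mse <- at$resid == "MSE"
  at$resid[sel_mse] <- "MET"
  at$elety[sel_mse & at$elety == "SE"] <- "SD"
  at$elesy[sel_mse & at$elesy == "SE"] <- "S"
  at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  at <- at[!(at$type == "HETATM" & !(at$resid %in% STANDARD_RESIDUES)), ,
           drop = FALSE]

  bad <- setdiff(unique(at$resid[at$type == "ATOM"]), STANDARD_RESIDUES)
  if (length(bad) > 0)
    stop("non-standard residue(s) in ATOM records: ",
         paste(bad, collapse = ", "))

  # drop hydrogens/deuterium
  elesy <- toupper(trimws(at$elesy))
  no_elem <- is.na(elesy) | elesy == ""
  elesy[no_elem] <- element_from_name(at$elety[no_elem])
  at$elesy <- elesy
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]

  # altloc: keep the highest-occupancy conformer per (residue, atom name)
  at$.ord <- seq_len(nrow(at))
  if (any(at$alt != "")) {
    ord <- order(residue_key(at$chain, at$resno, at$insert), at$elety,
                 -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    dup <- duplicated(paste(residue_key(at$chain, at$resno, at$insert),
                            at$elety))
    at <- at[!dup, , drop = FALSE]
    at <- at[order(at$.ord), , drop = FALSE]
  }

  chains <- unique(at$chain)
  for (p in list(partner1, partner2)) {
    missing <- setdiff(p, chains)
    if (length(missing) > 0)
      stop("chain(s) not present in ", path, ": ",
           paste(missing, collapse = ", "))
  }
  at <- at[at$chain %in% c(partner1, partner2), , drop = FALSE]

  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z)))
    stop("non-finite coordinates in ", path)

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = trimws(at$elety), elesy = at$elesy,
    x = at$x, y = at$y, z = at$z,
    partner = ifelse(at$chain %in% partner1, 1L, 2L),
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  new_ppi_structure(atoms, partner1, partner2)
}

#' Write a structure to a PDB file
#'
#' @param structure A `ppi_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   chain = a$chain, insert = a$insert,
                   elety = a$elety, elesy = a$elesy,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Per-residue table of a structure
#'
#' @param structure A `ppi_structure`.
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid`, `partner`.
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], partner = a$partner[first],
             stringsAsFactors = FALSE)
}

# Atoms of one residue, by key.
residue_atoms <- function(structure, key) {
  a <- structure$atoms
  a[residue_key(a$chain, a$resno, a$insert) == key, , drop = FALSE]
}

#' Apply a rigid transform to a structure
#'
#' Rotates then translates all atom coordinates: `x' = R x + t`. Used to
#' test the rigid-motion invariance of the cube representation.
#'
#' @param structure A `ppi_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector.
#' @return The transformed `ppi_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
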