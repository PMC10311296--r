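# Interface structural regions: interior, surface, support, core, rim.
#
# A residue's relative solvent accessibility (rASA) is computed twice: in
# the complex and in the "free" monomer obtained by deleting the partner's
# chains (rigid-body assumption, no relaxation). The five-region scheme of
# Levy (2010) then classifies each residue from the (rasa_complex,
# rasa_free) pair with a 25% rASA threshold.

REGION_LEVELS <- c("INT", "SUR", "SUP", "COR", "RIM")

#' Per-residue solvent accessibility in the bound and free states
#'
#' @param structure A `ppi_structure`.
#' @param probe Probe radius (A).
#' @param n_points SASA quadrature points per atom.
#' @param max_asa Reference maximal ASA table (named by 3-letter code);
#'   defaults to [max_asa_reference()].
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid`, `partner`, `asa_complex`, `asa_free`,
#'   `rasa_complex`, `rasa_free`.
#' @export
compute_accessibility <- function(structure, probe = 1.4, n_points = 256,
                                  max_asa = max_asa_reference()) {
  a <- structure$atoms
  res <- structure_residues(structure)
  if (length(unique(res$partner)) < 1 || nrow(res) == 0)
    stop("structure has no residues")
  missing_ref <- setdiff(unique(res$resid), names(max_asa))
  if (length(missing_ref) > 0)
    stop("residue type(s) absent from the maximal-ASA reference: ",
         paste(missing_ref, collapse = ", "))

  key_atoms <- residue_key(a$chain, a$resno, a$insert)
  xyz <- as.matrix(a[, c("x", "y", "z")])

  asa_cx_atom <- atom_sasa(xyz, a$elesy, probe, n_points)
  asa_complex <- rowsum(asa_cx_atom, key_atoms)[res$key, 1]

  # free state: each partner alone
  asa_free <- numeric(nrow(res))
  names(asa_free) <- res$key
  for (p in c(1L, 2L)) {
    sel <- a$partner == p
    if (!any(sel)) next
    asa_p_atom <- atom_sasa(xyz[sel, , drop = FALSE], a$elesy[sel],
                            probe, n_points)
    asa_p <- rowsum(asa_p_atom, key_atoms[sel])
    asa_free[rownames(asa_p)] <- asa_p[, 1]
  }

  res$asa_complex <- unname(asa_complex)
  res$asa_free <- unname(asa_free[res$key])
  res$rasa_complex <- res$asa_complex / unname(max_asa[res$resid])
  res$rasa_free <- res$asa_free / unname(max_asa[res$resid])
  res
}

#' Classify a residue into the five-region interface scheme
#'
#' Decision table (rASA threshold `theta` = 0.25; burial tolerance `delta`
#' in raw A^2 guards against quadrature noise):
#' no burial upon complexation -> INT if `rasa_complex < theta` else SUR;
#' burial -> SUP if `rasa_free < theta`; COR if `rasa_free >= theta` and
#' `rasa_complex < theta`; RIM if `rasa_complex >= theta`.
#'
#' @param rasa_complex,rasa_free Relative accessibilities (vectorized).
#' @param asa_complex,asa_free Raw accessibilities (A^2), used for the
#'   burial test; if omitted, the rASA difference is used against
#'   `delta = 0` equivalently scaled.
#' @param theta rASA threshold (default 0.25).
#' @param delta Burial tolerance on raw ASA, A^2 (default 0.1).
#' @return Factor with levels INT, SUR, SUP, COR, RIM.
#' @export
#' @examples
#' classify_region(0.10, 0.40)  # COR
classify_region <- function(rasa_complex, rasa_free,
                            asa_complex = NULL, asa_free = NULL,
                            theta = 0.25, delta = 0.1) {
  stopifnot(all(rasa_complex >= 0), all(rasa_free >= 0))
  if (is.null(asa_complex) || is.null(asa_free)) {
    buried <- (rasa_free - rasa_complex) > 0
  } else {
    buried <- (asa_free - asa_complex) > delta
  }
  lab <- ifelse(!buried,
                ifelse(rasa_complex < theta, "INT", "SUR"),
                ifelse(rasa_free < theta, "SUP",
                       ifelse(rasa_complex < theta, "COR", "RIM")))
  factor(lab, levels = REGION_LEVELS)
}

#' Region labels for every residue of a complex
#'
#' @param accessibility Output of [compute_accessibility()].
#' @inheritParams classify_region
#' @return The input data.frame with a `region` factor column added.
#' @export
assign_regions <- function(accessibility, theta = 0.25, delta = 0.1) {
  accessibility$region <- classify_region(
    accessibility$rasa_complex, accessibility$rasa_free,
    accessibility$asa_complex, accessibility$asa_free,
    theta = theta, delta = delta)
  accessibility
}

#' Interfacial residues of a complex
#'
#' Residues whose region is SUP, COR or RIM, i.e. exactly those burying
#' surface area upon complexation.
#'
#' @param structure A `ppi_structure`, or a precomputed
#'   [compute_accessibility()] table.
#' @param ... Passed to [compute_accessibility()] when a structure is given.
#' @return data.frame of interfacial residues (subset of the region table).
#'   Zero rows (with a warning) if the partners are not in contact.
#' @export
interface_residues <- function(structure, ...) {
  acc <- if (inherits(structure, "ppi_structure"))
    compute_accessibility(structure, ...) else structure
  acc <- assign_regions(acc)
  out <- acc[acc$region %in% c("SUP", "COR", "RIM"), , drop = FALSE]
  if (nrow(out) == 0)
    warning("no interfacial residues: the two partners do not bury surface")
  rownames(out) <- NULL
  out
}

#' Write the per-residue accessibility/region table as TSV
#'
#' @param regions Output of [assign_regions()] (or [interface_residues()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  cols <- c("chain", "resno", "insert", "resid", "asa_complex", "asa_free",
            "rasa_complex", "rasa_free", "region")
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
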