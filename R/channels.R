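# Atom -> channel encodings used by the voxel cubes.

#' Build an atom-type channel scheme
#'
#' Two encodings of atom identity are supported. `"full167"` assigns one
#' channel to every (residue type, heavy-atom name) pair of the 20 standard
#' amino acids: residues in alphabetical 3-letter order, atoms in topology
#' order (N, CA, C, O, then side chain), no OXT, no hydrogens. That
#' enumeration contains exactly 167 pairs. `"element4"` collapses atom
#' identity to the chemical element, 4 channels in the order C, N, O, S.
#'
#' @param mode `"full167"` or `"element4"`.
#' @return An object of class `channel_scheme` with fields `mode`,
#'   `n_channels`, and `channels` (a data.frame naming every channel).
#' @export
#' @examples
#' sc <- build_channel_scheme("full167")
#' sc$n_channels  # 167
build_channel_scheme <- function(mode = c("full167", "element4")) {
  mode <- match.arg(mode)
  if (mode == "full167") {
    topo <- residue_topology()
    channels <- data.frame(
      residue = rep(names(topo), lengths(topo)),
      atom = unlist(topo, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    channels$channel <- seq_len(nrow(channels))
    key <- paste(channels$residue, channels$atom)
  } else {
    channels <- data.frame(
      residue = NA_character_,
      atom = c("C", "N", "O", "S"),
      channel = 1:4,
      stringsAsFactors = FALSE
    )
    key <- channels$atom
  }
  structure(
    list(mode = mode,
         n_channels = nrow(channels),
         channels = channels,
         index = stats::setNames(channels$channel, key)),
    class = "channel_scheme"
  )
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("<channel_scheme> mode=%s, %d channels\n", x$mode, x$n_channels))
  invisible(x)
}

#' Channel index of an atom
#'
#' @param scheme A [build_channel_scheme()] object.
#' @param residue 3-letter residue code(s) (ignored for `element4`).
#' @param atom PDB atom name(s) for `full167`; for `element4` the element is
#'   derived from the atom name unless `element` is given.
#' @param element Optional element symbol(s), used for `element4`.
#' @return Integer channel indices in `1..n_channels`.
#' @export
#' @examples
#' sc <- build_channel_scheme("element4")
#' channel_index(sc, atom = "SG")  # sulfur channel
channel_index <- function(scheme, residue = NULL, atom, element = NULL) {
  stopifnot(inherits(scheme, "channel_scheme"))
  if (scheme$mode == "full167") {
    if (is.null(residue)) stop("full167 scheme requires residue codes")
    key <- paste(toupper(residue), toupper(trimws(atom)))
  } else {
    if (is.null(element)) element <- element_from_name(atom)
    key <- toupper(element)
  }
  idx <- scheme$index[key]
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("unknown atom(s) for channel scheme '", scheme$mode, "': ",
         paste(bad, collapse = ", "),
         " (nonstandard residue or malformed atom name)")
  }
  unname(idx)
}

#' Export a channel scheme as a plain-text table
#'
#' Writes a tab-separated table (channel, residue, atom) so a stored cube's
#' channel order can be audited outside R.
#'
#' @param scheme A [build_channel_scheme()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "channel_scheme"))
  utils::write.table(scheme$channels[, c("channel", "residue", "atom")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
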