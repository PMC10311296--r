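# Auxiliary per-residue / per-mutation descriptors.
#
# Five auxiliary features accompany each mutation: the wild-type residue's
# evolutionary conservation (t_jet, from a JET-style file), its interface
# physicochemical propensity (pc, bundled table), its protruding character
# (cv, circular variance), its structural region (sr, one-hot over
# INT/SUR/SUP/COR/RIM) and an alignment-based substitution score for the
# specific mutation (gemme, from a GEMME-style file). Encoded vector:
# [t_jet, pc, cv, sr x5, gemme], length 9.

#' Circular variance of a point relative to its neighbours
#'
#' `CV = 1 - || mean_j u_j ||` where `u_j` is the unit vector from the
#' center to neighbour j. Values near 0 indicate a protruding point (all
#' neighbours on one side), values near 1 a buried point (neighbours all
#' around). Invariant under rigid motions and neighbour permutation.
#'
#' @param center Length-3 coordinate.
#' @param neighbors n x 3 matrix of neighbour coordinates (n >= 1).
#' @return CV in `[0, 1]`.
#' @export
#' @examples
#' circular_variance(c(0, 0, 0), rbind(c(1, 0, 0)))           # 0
#' circular_variance(c(0, 0, 0), rbind(c(1, 0, 0), c(-1, 0, 0)))  # 1
circular_variance <- function(center, neighbors) {
  neighbors <- matrix(as.numeric(neighbors), ncol = 3)
  if (nrow(neighbors) < 1) stop("circular variance needs >= 1 neighbour")
  d <- sweep(neighbors, 2, as.numeric(center), "-")
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-9)) stop("neighbour coincides with the center")
  u <- d / nrm
  v <- colMeans(u)
  max(0, min(1, 1 - sqrt(sum(v^2))))
}

#' Circular variance of every residue of a structure
#'
#' The CV of a residue is computed at a representative atom (CA) against
#' the heavy atoms of all other residues within `cutoff` A.
#'
#' @param structure A `ppi_structure`.
#' @param cutoff Neighbour cutoff in A (default 12).
#' @return Named numeric vector keyed by residue key; `NA` for residues
#'   with no neighbour within the cutoff.
#' @export
residue_circular_variance <- function(structure, cutoff = 12) {
  a <- structure$atoms
  keys <- residue_key(a$chain, a$resno, a$insert)
  res <- structure_residues(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- stats::setNames(rep(NA_real_, nrow(res)), res$key)
  for (k in res$key) {
    ca <- a[keys == k & a$elety == "CA", c("x", "y", "z"), drop = FALSE]
    if (nrow(ca) != 1) next
    ctr <- as.numeric(ca[1, ])
    other <- keys != k
    d2 <- rowSums(sweep(xyz[other, , drop = FALSE], 2, ctr, "-")^2)
    nb <- xyz[other, , drop = FALSE][d2 <= cutoff^2, , drop = FALSE]
    if (nrow(nb) == 0) next
    out[k] <- circular_variance(ctr, nb)
  }
  out
}

AMINO_CLASSES <- list(
  ARO = c("F", "W", "Y", "H"),
  CAST = c("C", "A", "S", "T"),
  PHOB = c("I", "L", "M", "V"),
  POS = c("K", "R"),
  `POL-N` = c("N", "Q", "D", "E"),
  GLY = "G",
  PRO = "P"
)

#' Physicochemical similarity class of an amino acid
#'
#' Seven classes partitioning the 20 amino acids: ARO (F, W, Y, H),
#' CAST (C, A, S, T), PHOB (I, L, M, V), POS (K, R), POL-N (N, Q, D, E),
#' GLY (G), PRO (P).
#'
#' @param aa 1-letter code(s).
#' @return Factor with the seven class levels.
#' @export
#' @examples
#' amino_class("F")  # ARO
amino_class <- function(aa) {
  aa <- toupper(aa)
  map <- stats::setNames(rep(names(AMINO_CLASSES), lengths(AMINO_CLASSES)),
                         unlist(AMINO_CLASSES, use.names = FALSE))
  bad <- setdiff(unique(aa), names(map))
  if (length(bad) > 0)
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  factor(unname(map[aa]), levels = names(AMINO_CLASSES))
}

#' Size-change class of a substitution
#'
#' The volume difference `dV = V(mut) - V(wt)` classifies a mutation as
#' size-neutral (`|dV| < 10` A^3), small-to-large (`dV > 10`) or
#' large-to-small (`dV < -10`).
#'
#' @param wt,mut 1-letter codes (vectorized).
#' @param volumes Named volume table in A^3, default
#'   [residue_volume_reference()].
#' @param threshold Volume threshold in A^3 (default 10).
#' @return Factor with levels `size-neutral`, `small-to-large`,
#'   `large-to-small`.
#' @export
size_change_class <- function(wt, mut, volumes = residue_volume_reference(),
                              threshold = 10) {
  wt <- toupper(wt); mut <- toupper(mut)
  bad <- setdiff(unique(c(wt, mut)), names(volumes))
  if (length(bad) > 0)
    stop("amino acid(s) absent from the volume table: ",
         paste(bad, collapse = ", "))
  dv <- unname(volumes[mut] - volumes[wt])
  lab <- ifelse(abs(dv) < threshold, "size-neutral",
                ifelse(dv > 0, "small-to-large", "large-to-small"))
  factor(lab, levels = c("size-neutral", "small-to-large", "large-to-small"))
}

# Strict tabular reader shared by the conservation and substitution-score
# parsers: whitespace/TSV dialect with a header.
.read_score_table <- function(path, required) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("score file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  tab
}

#' Load per-residue conservation levels (JET-style file)
#'
#' Expects a whitespace- or tab-separated file with header columns
#' `chain`, `resno`, `tjet` (extra columns ignored).
#'
#' @param path File path.
#' @return Named numeric vector keyed by residue key (`chain|resno|`).
#' @export
load_conservation <- function(path) {
  tab <- .read_score_table(path, c("chain", "resno", "tjet"))
  key <- residue_key(tab$chain, tab$resno)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(tab$tjet[key == k])) > 1
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate conservation entries for: ",
           paste(unique(key[dup])[conflict], collapse = ", "))
    tab <- tab[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  stats::setNames(as.numeric(tab$tjet), key)
}

#' Load per-mutation substitution scores (GEMME-style file)
#'
#' Expects header columns `chain`, `resno`, `mut`, `score`.
#'
#' @param path File path.
#' @return Named numeric vector keyed by `chain|resno||mut`.
#' @export
load_gemme <- function(path) {
  tab <- .read_score_table(path, c("chain", "resno", "mut", "score"))
  key <- paste(residue_key(tab$chain, tab$resno), toupper(tab$mut),
               sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(tab$score[key == k])) > 1
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate substitution-score entries for: ",
           paste(unique(key[dup])[conflict], collapse = ", "))
    tab <- tab[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  stats::setNames(as.numeric(tab$score), key)
}

#' Look up scores for a set of required keys
#'
#' Strict companion to [load_conservation()] / [load_gemme()]: returns the
#' values for `keys` and fails with the full list of missing keys rather
#' than propagating `NA`s into a feature matrix.
#'
#' @param scores Named numeric vector (as returned by the loaders).
#' @param keys Character keys that must all be present.
#' @return Numeric values in the order of `keys`.
#' @export
lookup_scores <- function(scores, keys) {
  v <- scores[keys]
  if (anyNA(v))
    stop("score file lacks entries for: ",
         paste(keys[is.na(v)], collapse = ", "))
  unname(v)
}

SR_ONEHOT_ORDER <- c("INT", "SUR", "SUP", "COR", "RIM")

#' Assemble the encoded auxiliary feature vector of a mutation
#'
#' Fixed order: `[t_jet, pc, cv, sr(INT), sr(SUR), sr(SUP), sr(COR),
#' sr(RIM), gemme]`, length 9. The first four features describe the
#' wild-type residue; the substitution score is mutation-specific. Ablation
#' configurations keep the vector length fixed and zero the excluded
#' scalar slots: `"SR"` keeps only the one-hot, `"SR-Tjet"` adds t_jet,
#' `"SR-GEMME"` adds the substitution score, `"All"` keeps everything.
#'
#' @param t_jet Conservation level in `[0, 1]`.
#' @param pc Interface propensity scalar.
#' @param cv Circular variance in `[0, 1]`.
#' @param sr Region label (one of INT, SUR, SUP, COR, RIM).
#' @param gemme Substitution score.
#' @param config Ablation configuration (default `"All"`).
#' @return Numeric vector of length 9.
#' @export
#' @examples
#' assemble_aux(0.8, 0.3, 0.5, "COR", -1.2)
assemble_aux <- function(t_jet, pc, cv, sr, gemme,
                         config = c("All", "SR", "SR-Tjet", "SR-GEMME")) {
  config <- match.arg(config)
  sr <- as.character(sr)
  if (!sr %in% SR_ONEHOT_ORDER)
    stop("unknown structural region: ", sr)
  vals <- list(t_jet = t_jet, pc = pc, cv = cv, gemme = gemme)
  bad <- names(vals)[!vapply(vals, function(v)
    length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad) > 0)
    stop("missing/non-finite auxiliary feature(s): ",
         paste(bad, collapse = ", "))
  keep <- switch(config,
                 All = c("t_jet", "pc", "cv", "gemme"),
                 SR = character(0),
                 `SR-Tjet` = "t_jet",
                 `SR-GEMME` = "gemme")
  scal <- c(t_jet = 0, pc = 0, cv = 0, gemme = 0)
  scal[keep] <- unlist(vals)[keep]
  onehot <- as.numeric(SR_ONEHOT_ORDER == sr)
  out <- c(scal["t_jet"], scal["pc"], scal["cv"], onehot, scal["gemme"])
  names(out) <- c("t_jet", "pc", "cv", paste0("sr_", SR_ONEHOT_ORDER),
                  "gemme")
  out
}

#' Min-max scale auxiliary scalars over a training set
#'
#' Scales the four scalar slots of a matrix of encoded auxiliary vectors to
#' `[0, 1]` using ranges estimated on the training rows; one-hot slots are
#' untouched. Constant columns are left unscaled.
#'
#' @param aux Matrix (rows = samples, 9 columns as from [assemble_aux()]).
#' @param ranges Optional precomputed list `(min, max)`; if missing,
#'   estimated from `aux`.
#' @return List `scaled` (matrix) and `ranges` (to apply to new data).
#' @export
scale_aux <- function(aux, ranges = NULL) {
  aux <- as.matrix(aux)
  scalar_cols <- c(1, 2, 3, 9)
  if (is.null(ranges)) {
    ranges <- list(min = apply(aux[, scalar_cols, drop = FALSE], 2, min),
                   max = apply(aux[, scalar_cols, drop = FALSE], 2, max))
  }
  span <- ranges$max - ranges$min
  for (j in seq_along(scalar_cols)) {
    if (span[j] > 1e-12)
      aux[, scalar_cols[j]] <-
        (aux[, scalar_cols[j]] - ranges$min[j]) / span[j]
  }
  list(scaled = aux, ranges = ranges)
}
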