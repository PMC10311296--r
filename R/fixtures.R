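# Deterministic synthetic fixtures.
#
# These generators produce small, fully synthetic inputs with known ground
# truth so the whole pipeline (parsing, accessibility, regions, cubes,
# masking, networks, metrics) can be exercised offline: a two-chain toy
# complex with a controlled contact patch, labeled masked cubes with
# planted amino-acid-specific environments, and wild-type/mutant cube
# pairs whose ddG target is a known linear function of a cube-visible
# quantity plus noise. Geometry is idealized, not physically realistic:
# the consumers only require consistent, reproducible shapes.

# Backbone + compact side-chain template of one residue, relative to CA.
# `side` = +1 / -1 flips the side-chain direction (partner A vs B).
.residue_template <- function(resid, side = 1) {
  topo <- residue_topology()[[resid]]
  if (is.null(topo)) stop("unknown residue type: ", resid)
  pos <- rbind(
    N = c(-1.46, 0, 0),
    CA = c(0, 0, 0),
    C = c(0.55, 0, 1.42),
    O = c(0.75, 0, 2.60)
  )
  side_atoms <- setdiff(topo, rownames(pos))
  for (j in seq_along(side_atoms)) {
    # compact helical blob reaching ~2.2 A beyond CB toward the partner
    layer <- (j - 1) %/% 3
    ang <- j * 2.399963  # golden angle, avoids collinear stacking
    pos <- rbind(pos, c(0.45 * sin(ang),
                        1.53 + 0.7 + 0.5 * layer,
                        0.45 * cos(ang)))
    rownames(pos)[nrow(pos)] <- side_atoms[j]
  }
  if ("CB" %in% side_atoms) pos["CB", ] <- c(0, 1.53, 0)
  pos[, 2] <- pos[, 2] * side
  pos
}

#' Generate a synthetic two-chain complex with a known contact patch
#'
#' Two chains of idealized residues run along x; the last `patch` residues
#' of each chain (offset by an x-jump so they cannot graze the rest) face
#' each other across a `gap` A separation of the CA lines, with side
#' chains pointing inward. With the default gap the patch residues -- and
#' only they -- bury solvent-accessible surface upon complexation; with a
#' large gap the chains do not touch at all.
#'
#' @param n_res Residues per chain (default 8).
#' @param patch Contact-patch residues per chain (default 3); the expected
#'   interfacial residues are the patch of both chains (2 * patch keys).
#' @param gap Distance between the two CA lines in A (default 9; use
#'   something large, e.g. 100, for a non-contacting pair).
#' @param seed Seed for the small deterministic coordinate jitter.
#' @param pdb_path Optional path: also write the complex as a PDB file.
#' @return A `ppi_structure` (chains "A" and "B") with attribute
#'   `patch_keys` giving the constructed interface residue keys.
#' @export
make_toy_complex <- function(n_res = 8, patch = 3, gap = 9, seed = 1L,
                             pdb_path = NULL) {
  if (patch > n_res) stop("patch size exceeds chain length")
  if (patch < 1) stop("patch must have at least one residue")
  if (gap < 7) stop("gap below 7 A would fuse the backbones: infeasible")
  set.seed(seed)
  jump <- 12  # x separation insulating the patch from the rest
  seqs <- list(A = STANDARD_RESIDUES[(seq_len(n_res) - 1) %% 20 + 1],
               B = STANDARD_RESIDUES[(seq_len(n_res) + 6) %% 20 + 1])
  # patch residues get long/bulky side chains so the two patches reliably
  # bury surface across the gap
  bulky <- c("TRP", "ARG", "TYR", "LYS", "PHE", "GLU")
  for (ch in c("A", "B")) {
    ip <- which(seq_len(n_res) > n_res - patch)
    seqs[[ch]][ip] <- bulky[(ip + (ch == "B") * 3 - 1) %% 6 + 1]
  }
  rows <- list()
  patch_keys <- character(0)
  for (chain in c("A", "B")) {
    side <- if (chain == "A") 1 else -1
    y0 <- if (chain == "A") 0 else gap
    for (i in seq_len(n_res)) {
      in_patch <- i > n_res - patch
      x0 <- (i - 1) * 3.8 + if (in_patch) jump else 0
      yres <- y0 + if (chain == "B" && !in_patch) 25 else 0
      tmpl <- .residue_template(seqs[[chain]][i], side)
      jit <- matrix(stats::runif(length(tmpl), -0.02, 0.02), nrow(tmpl))
      xyz <- tmpl + jit
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = i, insert = "",
        resid = seqs[[chain]][i],
        elety = rownames(tmpl),
        elesy = element_from_name(rownames(tmpl)),
        x = round(xyz[, 1] + x0, 3),
        y = round(xyz[, 2] + yres, 3),
        z = round(xyz[, 3], 3),
        partner = if (chain == "A") 1L else 2L,
        stringsAsFactors = FALSE
      )
      if (in_patch)
        patch_keys <- c(patch_keys, residue_key(chain, i, ""))
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  st <- new_ppi_structure(atoms, "A", "B")
  attr(st, "patch_keys") <- patch_keys
  if (!is.null(pdb_path)) write_pdb(st, pdb_path)
  st
}

# Shared helper: central-residue atoms (backbone + CB) at the frame origin.
.center_residue_atoms <- function(resid3, key = "X|1|") {
  resid3 <- unname(resid3)
  tmpl <- .residue_template("ALA", 1)  # backbone + CB scaffold
  keep <- intersect(rownames(tmpl), residue_topology()[[resid3]])
  m <- unname(tmpl[keep, , drop = FALSE])
  data.frame(chain = "X", resno = 1L, insert = "", resid = resid3,
             elety = keep, elesy = element_from_name(keep),
             lx = m[, 1], ly = m[, 2], lz = m[, 3],
             is_center = TRUE, stringsAsFactors = FALSE)
}

# Environment atoms on a sphere around the origin with a per-class count
# and element pattern. Channel identity is carried by small standard
# residue/atom name pairs so both schemes can encode them.
.environment_atoms <- function(n_atoms, radius, elem_offset, jitter_sd) {
  pts <- fibonacci_sphere(n_atoms) * radius
  pts <- pts + matrix(stats::rnorm(length(pts), sd = jitter_sd), n_atoms)
  elems <- c("C", "N", "O", "S")[(elem_offset + seq_len(n_atoms)) %% 4 + 1]
  carrier <- list(C = c("GLY", "CA"), N = c("GLY", "N"),
                  O = c("GLY", "O"), S = c("CYS", "SG"))
  resid <- unname(vapply(elems, function(e) carrier[[e]][1], character(1)))
  elety <- unname(vapply(elems, function(e) carrier[[e]][2], character(1)))
  data.frame(chain = "E", resno = 1L + seq_len(n_atoms), insert = "",
             resid = resid, elety = elety, elesy = elems,
             lx = pts[, 1], ly = pts[, 2], lz = pts[, 3],
             is_center = FALSE, stringsAsFactors = FALSE)
}

.as_cube <- function(atoms, center = "X|1|", n_voxels = 24,
                     voxel_side = 0.8) {
  list(atoms = atoms, center = center,
       frame = list(origin = c(0, 0, 0), axes = diag(3)),
       n_voxels = n_voxels, voxel_side = voxel_side)
}

#' Generate labeled masked cubes with planted environments
#'
#' Sample i carries the amino-acid label cycling through the 20 types.
#' Each label is planted a distinctive local environment: a spherical
#' shell of atoms at 7.8 A whose atom count (and element pattern) encodes
#' the class, plus the central residue's own scaffold. The standard
#' self-supervision mask (5 A sphere around a randomly chosen central
#' atom) is then applied: it removes the whole central scaffold but never
#' reaches the shell, so the label stays recoverable from the masked cube.
#'
#' @param n Number of cubes (>= 20 so every class occurs).
#' @param scheme A [build_channel_scheme()] object.
#' @param seed Seed (per-sample jitter and mask centers derive from it).
#' @param mask_radius Mask sphere radius in A (default 5).
#' @return List: `cubes` (masked `cube_map`s), `labels` (1-letter codes),
#'   `raw_cubes` (unmasked cube atom sets) and `masked_cubes` (after
#'   [mask_sphere()], before voxelization).
#' @export
make_labeled_cubes <- function(n, scheme, seed = 1L, mask_radius = 5) {
  if (n < 20) stop("need n >= 20 to cover the amino-acid classes")
  one3 <- aa_one_to_three()
  labels <- AA_LEVELS[(seq_len(n) - 1) %% 20 + 1]
  raw <- vector("list", n)
  masked <- vector("list", n)
  cubes <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + 17L * i)
    idx <- match(labels[i], AA_LEVELS)
    atoms <- rbind(.center_residue_atoms(one3[labels[i]]),
                   .environment_atoms(8L + idx, 7.8, idx, 0.25))
    cube <- .as_cube(atoms)
    raw[[i]] <- cube
    masked[[i]] <- mask_sphere(cube, radius = mask_radius,
                               center_policy = "random",
                               seed = seed + 31L * i)
    cubes[[i]] <- voxelize(masked[[i]], scheme)
  }
  list(cubes = cubes, labels = labels, raw_cubes = raw,
       masked_cubes = masked)
}

#' Generate a synthetic ddG dataset with known ground truth
#'
#' Pair i consists of a wild-type and a mutant cube sharing the same
#' environment shell but differing in the number of atoms planted in the
#' central residue's sphere (counts `k_wt`, `k_mu` between 3 and 9, at
#' radius 2.5 A). The target is the planted linear model
#' `ddg = alpha * (k_wt - k_mu) + beta * gemme + noise`, where `gemme`
#' is the mutation-specific auxiliary scalar (slot 9 of the encoded
#' auxiliary vector) and the noise is Gaussian with sd `noise_sd`.
#' `alpha` and `beta` are recorded so recovery can be verified.
#'
#' @param n Number of pairs (>= 20).
#' @param noise_sd Noise standard deviation in kcal/mol (default 0.3).
#' @param seed Seed.
#' @param scheme Channel scheme (default `element4`).
#' @param alpha,beta Planted coefficients (defaults 0.5 and 1).
#' @return List: `wt_cubes`, `mu_cubes`, `aux` (n x 9 matrix), `targets`,
#'   `alpha`, `beta`, `k_wt`, `k_mu`.
#' @export
make_synthetic_ddg <- function(n, noise_sd = 0.3, seed = 1L,
                               scheme = build_channel_scheme("element4"),
                               alpha = 0.5, beta = 1) {
  if (n < 20) stop("need n >= 20 synthetic pairs")
  set.seed(seed)
  k_wt <- sample(3:9, n, replace = TRUE)
  k_mu <- sample(3:9, n, replace = TRUE)
  gemme <- stats::runif(n, -2, 2)
  sr <- sample(c("SUP", "COR", "RIM"), n, replace = TRUE)
  noise <- stats::rnorm(n, sd = noise_sd)
  targets <- alpha * (k_wt - k_mu) + beta * gemme + noise
  wt_cubes <- vector("list", n)
  mu_cubes <- vector("list", n)
  aux <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    set.seed(seed + 101L * i)
    env <- .environment_atoms(12L, 7.8, i %% 4, 0.25)
    make_side <- function(k, sub_seed) {
      set.seed(sub_seed)
      pts <- fibonacci_sphere(k) * 2.5
      pts <- pts + matrix(stats::rnorm(length(pts), sd = 0.15), k)
      core <- data.frame(chain = "X", resno = 1L, insert = "",
                         resid = "GLY",
                         elety = rep("CA", k), elesy = rep("C", k),
                         lx = pts[, 1], ly = pts[, 2], lz = pts[, 3],
                         is_center = TRUE, stringsAsFactors = FALSE)
      voxelize(.as_cube(rbind(core, env)), scheme)
    }
    wt_cubes[[i]] <- make_side(k_wt[i], seed + 101L * i + 1L)
    mu_cubes[[i]] <- make_side(k_mu[i], seed + 101L * i + 2L)
    aux[i, ] <- assemble_aux(t_jet = stats::runif(1), pc = 0,
                             cv = stats::runif(1), sr = sr[i],
                             gemme = gemme[i])
  }
  colnames(aux) <- c("t_jet", "pc", "cv", paste0("sr_", SR_ONEHOT_ORDER),
                     "gemme")
  list(wt_cubes = wt_cubes, mu_cubes = mu_cubes, aux = aux,
       targets = targets, alpha = alpha, beta = beta,
       k_wt = k_wt, k_mu = k_mu)
}
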