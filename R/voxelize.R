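# Locally oriented residue-centered voxel cubes.
#
# Each interfacial residue defines a local orthonormal frame from its
# backbone N, CA, C atoms (the chemical scaffold shared by all amino
# acids). Atoms of both partners falling inside a 24 x 24 x 24 voxel cube
# of 0.8 A voxels (19.2 A per side, centered on CA) are projected onto the
# grid as truncated-Gaussian densities, one channel per atom type. The
# representation is invariant to rigid motions of the input structure
# because all coordinates are expressed in the local frame.

#' Build the backbone local frame of a residue
#'
#' origin = CA; e1 = unit(N - CA); e3 = unit(e1 x (C - CA)); e2 = e3 x e1.
#' Uses backbone atoms only, so it is defined for every amino acid
#' including glycine, and is equivariant under rigid motions.
#'
#' @param n_xyz,ca_xyz,c_xyz Length-3 coordinates of the backbone N, CA, C.
#' @return List with `origin` (length 3) and `axes` (3x3 rotation matrix,
#'   rows = local basis vectors e1, e2, e3).
#' @export
#' @examples
#' f <- build_local_frame(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
#' f$axes  # identity
build_local_frame <- function(n_xyz, ca_xyz, c_xyz) {
  n_xyz <- as.numeric(n_xyz); ca_xyz <- as.numeric(ca_xyz)
  c_xyz <- as.numeric(c_xyz)
  stopifnot(length(n_xyz) == 3, length(ca_xyz) == 3, length(c_xyz) == 3)
  e1 <- n_xyz - ca_xyz
  n1 <- sqrt(sum(e1^2))
  v <- c_xyz - ca_xyz
  if (n1 < 1e-8 || sqrt(sum(v^2)) < 1e-8)
    stop("degenerate backbone: coincident atoms")
  e1 <- e1 / n1
  e3 <- c(e1[2] * v[3] - e1[3] * v[2],
          e1[3] * v[1] - e1[1] * v[3],
          e1[1] * v[2] - e1[2] * v[1])
  n3 <- sqrt(sum(e3^2))
  if (n3 < 1e-8) stop("collinear backbone atoms: frame undefined")
  e3 <- e3 / n3
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(origin = as.numeric(ca_xyz),
       axes = rbind(e1 = e1, e2 = e2, e3 = e3))
}

# Frame for a residue of a structure, by key. Returns NULL (with a warning)
# when a backbone atom is missing.
residue_frame <- function(structure, key) {
  ra <- residue_atoms(structure, key)
  get1 <- function(name) {
    m <- ra[ra$elety == name, c("x", "y", "z"), drop = FALSE]
    if (nrow(m) != 1) return(NULL)
    as.numeric(m[1, ])
  }
  n <- get1("N"); ca <- get1("CA"); cc <- get1("C")
  if (is.null(n) || is.null(ca) || is.null(cc)) {
    warning("residue ", key, " lacks a backbone atom; skipped")
    return(NULL)
  }
  build_local_frame(n, ca, cc)
}

#' Atoms of a complex expressed in a residue's local frame, restricted to
#' the cube
#'
#' Returns every heavy atom of either partner whose frame-local coordinates
#' fall inside the cube extent `[-half, half)` on each axis (half-open,
#' lower-inclusive), where `half = n_voxels * voxel_side / 2`.
#'
#' @param structure A `ppi_structure`.
#' @param center Residue key of the cube center.
#' @param n_voxels Voxels per side (default 24).
#' @param voxel_side Voxel edge length in A (default 0.8).
#' @return List with `atoms` (atom table plus local coordinates `lx`, `ly`,
#'   `lz`), `frame`, `center`, `n_voxels`, `voxel_side`. The flag
#'   `is_center` marks atoms of the center residue.
#' @export
extract_cube_atoms <- function(structure, center, n_voxels = 24,
                               voxel_side = 0.8) {
  frame <- residue_frame(structure, center)
  if (is.null(frame)) stop("cannot build frame for residue ", center)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  local <- sweep(xyz, 2, frame$origin, "-") %*% t(frame$axes)
  half <- n_voxels * voxel_side / 2
  inside <- local[, 1] >= -half & local[, 1] < half &
    local[, 2] >= -half & local[, 2] < half &
    local[, 3] >= -half & local[, 3] < half
  atoms <- a[inside, , drop = FALSE]
  atoms$lx <- local[inside, 1]
  atoms$ly <- local[inside, 2]
  atoms$lz <- local[inside, 3]
  atoms$is_center <- residue_key(atoms$chain, atoms$resno,
                                 atoms$insert) == center
  rownames(atoms) <- NULL
  list(atoms = atoms, frame = frame, center = center,
       n_voxels = n_voxels, voxel_side = voxel_side)
}

#' Mask a sphere around the central residue
#'
#' Implements the self-supervision mask: a sphere of radius `radius` A
#' centered on an atom of the central residue is emptied; every atom (from
#' any residue or partner) whose center lies strictly inside the sphere is
#' removed; atoms at exactly the radius are kept. Masking a fixed volume
#' avoids leaking amino-acid-specific size or shape.
#'
#' @param cube Output of [extract_cube_atoms()].
#' @param radius Mask radius in A (default 5).
#' @param center_policy `"random"` (uniform over the central residue's
#'   heavy atoms), `"CA"`, or `"CB"` (falls back to CA for glycine).
#' @param seed Integer seed making the random policy reproducible.
#' @return The cube with masked atoms removed; the chosen sphere center and
#'   mask parameters are recorded in `cube$mask`.
#' @export
mask_sphere <- function(cube, radius = 5,
                        center_policy = c("random", "CA", "CB"),
                        seed = 1L) {
  center_policy <- match.arg(center_policy)
  stopifnot(radius > 0)
  at <- cube$atoms
  ca_at <- at[at$is_center, , drop = FALSE]
  if (nrow(ca_at) == 0) stop("central residue has no atoms in the cube")
  pick <- switch(
    center_policy,
    CA = which(ca_at$elety == "CA"),
    CB = {
      w <- which(ca_at$elety == "CB")
      if (length(w) == 0) which(ca_at$elety == "CA") else w
    },
    random = {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      set.seed(seed)
      w <- sample.int(nrow(ca_at), 1)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      w
    }
  )
  if (length(pick) == 0) stop("mask center atom not found in cube")
  ctr <- as.numeric(ca_at[pick[1], c("lx", "ly", "lz")])
  d <- sqrt((at$lx - ctr[1])^2 + (at$ly - ctr[2])^2 + (at$lz - ctr[3])^2)
  cube$atoms <- at[d >= radius, , drop = FALSE]
  rownames(cube$atoms) <- NULL
  cube$mask <- list(radius = radius, center_policy = center_policy,
                    seed = seed, center = ctr)
  cube
}

# Per-axis integral of the truncated (+renormalized) Gaussian kernel over
# voxel intervals. Kernel support is [-cut, cut] around the atom; within it
# the 1D factor is a truncated normal, so the full 3D kernel integrates to
# exactly 1 over its support.
.axis_weights <- function(pos, edges, sigma, cut) {
  lo <- pmax(edges[-length(edges)], pos - cut)
  hi <- pmin(edges[-1], pos + cut)
  w <- numeric(length(lo))
  ok <- hi > lo
  if (any(ok)) {
    z <- stats::pnorm(c(hi[ok], lo[ok]), mean = pos, sd = sigma)
    m <- sum(ok)
    norm <- stats::pnorm(cut / sigma) - stats::pnorm(-cut / sigma)
    w[ok] <- (z[seq_len(m)] - z[m + seq_len(m)]) / norm
  }
  w
}

#' Project cube atoms onto the voxel grid
#'
#' Each atom contributes a separable truncated-Gaussian density
#' (sd `sigma`, truncated at `trunc_sd` standard deviations per axis and
#' renormalized) to its channel; per-voxel values are the analytic integral
#' of the kernel over the voxel box, summed over atoms. An atom whose
#' kernel support lies fully inside the grid therefore deposits a total
#' mass of exactly 1.
#'
#' @param cube Output of [extract_cube_atoms()] (optionally masked).
#' @param scheme A [build_channel_scheme()] object.
#' @param sigma Kernel standard deviation in A (default = voxel side).
#' @param trunc_sd Truncation half-width in standard deviations (default 2).
#' @return A `cube_map`: 4D array `[x, y, z, channel]` plus metadata
#'   (`center`, `frame`, `scheme_mode`, `voxel_side`, `mask`).
#' @export
voxelize <- function(cube, scheme, sigma = NULL, trunc_sd = 2) {
  stopifnot(inherits(scheme, "channel_scheme"))
  n <- cube$n_voxels
  side <- cube$voxel_side
  if (is.null(sigma)) sigma <- side
  cut <- trunc_sd * sigma
  half <- n * side / 2
  edges <- seq(-half, half, by = side)
  grid <- array(0, dim = c(n, n, n, scheme$n_channels))
  at <- cube$atoms
  if (nrow(at) > 0) {
    ch <- channel_index(scheme, residue = at$resid, atom = at$elety,
                        element = at$elesy)
    for (i in seq_len(nrow(at))) {
      wx <- .axis_weights(at$lx[i], edges, sigma, cut)
      wy <- .axis_weights(at$ly[i], edges, sigma, cut)
      wz <- .axis_weights(at$lz[i], edges, sigma, cut)
      ix <- which(wx > 0); iy <- which(wy > 0); iz <- which(wz > 0)
      if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) next
      block <- outer(outer(wx[ix], wy[iy]), wz[iz])
      grid[ix, iy, iz, ch[i]] <- grid[ix, iy, iz, ch[i]] + block
    }
  }
  structure(list(grid = grid, n_voxels = n, voxel_side = side,
                 sigma = sigma, trunc_sd = trunc_sd,
                 center = cube$center, frame = cube$frame,
                 scheme_mode = scheme$mode,
                 n_channels = scheme$n_channels,
                 mask = cube$mask),
            class = "cube_map")
}

#' @export
print.cube_map <- function(x, ...) {
  cat(sprintf("<cube_map> %d^3 voxels (%.1f A side), %d channels (%s), center %s\n",
              x$n_voxels, x$voxel_side, x$n_channels, x$scheme_mode,
              x$center %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build all interface cubes of a complex
#'
#' Convenience driver: finds the interfacial residues, then extracts,
#' optionally masks and voxelizes one cube per residue.
#'
#' @param structure A `ppi_structure`.
#' @param scheme A [build_channel_scheme()] object.
#' @param mask `NULL` for no masking, or a list with entries `radius`,
#'   `center_policy`, `seed` passed to [mask_sphere()] (the per-cube seed is
#'   offset by the cube index so each cube draws its own center).
#' @param ... Passed to [compute_accessibility()].
#' @return Named list of `cube_map` objects keyed by residue key; each
#'   carries its region label in `$region`.
#' @export
interface_cubes <- function(structure, scheme, mask = NULL, ...) {
  ifres <- interface_residues(structure, ...)
  out <- list()
  for (i in seq_len(nrow(ifres))) {
    key <- ifres$key[i]
    cube <- tryCatch(extract_cube_atoms(structure, key),
                     error = function(e) NULL)
    if (is.null(cube)) next
    if (!is.null(mask))
      cube <- mask_sphere(cube, radius = mask$radius %||% 5,
                          center_policy = mask$center_policy %||% "random",
                          seed = (mask$seed %||% 1L) + i)
    cm <- voxelize(cube, scheme)
    cm$region <- as.character(ifres$region[i])
    out[[key]] <- cm
  }
  out
}

#' Persist cubes to disk / load them back
#'
#' Cubes are stored as an RDS container holding the list of `cube_map`
#' objects and a metadata record (channel scheme mode, mask parameters,
#' creation time).
#'
#' @param cubes Named list of `cube_map` objects.
#' @param path Output `.rds` path.
#' @return `path` (save) / the cube list (load), invisibly for save.
#' @export
save_cubes <- function(cubes, path) {
  meta <- list(scheme_mode = if (length(cubes)) cubes[[1]]$scheme_mode else NA,
               n = length(cubes))
  saveRDS(list(meta = meta, cubes = cubes), path)
  invisible(path)
}

#' @rdname save_cubes
#' @export
load_cubes <- function(path) {
  readRDS(path)$cubes
}
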