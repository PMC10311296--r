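# Shrake-Rupley solvent-accessible surface area.
#
# Rolling-probe SASA by numerical quadrature: each atom's solvent-accessible
# sphere (radius = vdW + probe) is sampled with a deterministic Fibonacci
# point set; a point is accessible if it lies outside every neighbour's
# accessible sphere. ASA = accessible fraction * sphere area.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley SASA with a 1.4 A water probe, Bondi-type van der Waals
#' radii for C/N/O/S and a deterministic Fibonacci sphere quadrature.
#'
#' @param xyz n x 3 coordinate matrix (A).
#' @param elements Character vector of element symbols (C, N, O, S).
#' @param probe Probe radius in A (default 1.4).
#' @param n_points Quadrature points per atom (default 256).
#' @return Numeric vector of per-atom ASA values (A^2).
#' @export
atom_sasa <- function(xyz, elements, probe = 1.4, n_points = 256) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(elements))
  radii <- vdw_radii[toupper(elements)]
  if (anyNA(radii))
    stop("unknown element(s) for SASA radii: ",
         paste(unique(elements[is.na(radii)]), collapse = ", "))
  radii <- unname(radii) + probe
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  asa <- numeric(n)
  max_r <- max(radii)
  for (i in seq_len(n)) {
    ri <- radii[i]
    # neighbours whose accessible spheres can occlude atom i's sphere
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (ri + max_r)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (ri + radii[nb])^2]
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp <- sweep(sp, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- rowSums(sweep(sp[accessible, , drop = FALSE], 2,
                           xyz[j, ], "-")^2)
      accessible[accessible] <- dj2 >= radii[j]^2
    }
    asa[i] <- 4 * pi * ri^2 * sum(accessible) / n_points
  }
  asa
}
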