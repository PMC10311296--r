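# Local frames, cube extraction, Gaussian voxelization and masking.

test_that("the backbone frame reproduces the hand-computed basis", {
  f <- build_local_frame(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(unname(f$axes[1, ]), c(1, 0, 0))
  expect_equal(unname(f$axes[2, ]), c(0, 1, 0))
  expect_equal(unname(f$axes[3, ]), c(0, 0, 1))
  expect_equal(f$origin, c(0, 0, 0))
})

test_that("frames are orthonormal, right-handed and rigid-motion equivariant", {
  set.seed(11)
  for (i in 1:10) {
    n <- rnorm(3); ca <- rnorm(3); cc <- rnorm(3)
    f <- build_local_frame(n, ca, cc)
    expect_equal(f$axes %*% t(f$axes), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(det(f$axes), 1, tolerance = 1e-10)
    R <- random_rotation(i); t <- rnorm(3)
    f2 <- build_local_frame(R %*% n + t, R %*% ca + t, R %*% cc + t)
    p <- rnorm(3)  # any point, expressed in each frame
    local1 <- f$axes %*% (p - f$origin)
    local2 <- f2$axes %*% (R %*% p + t - f2$origin)
    expect_equal(local1, local2, tolerance = 1e-6)
  }
})

test_that("collinear backbone atoms are rejected", {
  expect_error(build_local_frame(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("cube extraction keeps nearby atoms of both partners only", {
  st <- toy_complex(1)
  key <- attr(st, "patch_keys")[1]
  cube <- extract_cube_atoms(st, key)
  expect_setequal(unique(cube$atoms$partner), c(1L, 2L))
  expect_true(any(cube$atoms$is_center))
  half <- cube$n_voxels * cube$voxel_side / 2
  expect_true(all(abs(cube$atoms[, c("lx", "ly", "lz")]) <= half))
  # an atom 50 A away from every center must never appear
  far <- st
  far$atoms <- rbind(far$atoms, within(far$atoms[1, ], {
    x <- x + 50; elety <- "CB"; resno <- 999L
  }))
  cube2 <- extract_cube_atoms(far, key)
  expect_false(any(cube2$atoms$resno == 999L))
})

test_that("voxelization conserves per-atom density mass", {
  sc <- build_channel_scheme("element4")
  empty <- list(atoms = data.frame(), n_voxels = 24, voxel_side = 0.8,
                center = "x", frame = NULL)
  empty$atoms <- data.frame(chain = character(), resno = integer(),
                            insert = character(), resid = character(),
                            elety = character(), elesy = character(),
                            lx = numeric(), ly = numeric(), lz = numeric(),
                            is_center = logical())
  expect_equal(sum(voxelize(empty, sc)$grid), 0)

  one <- empty
  one$atoms <- data.frame(chain = "A", resno = 1L, insert = "",
                          resid = "ALA", elety = "CA", elesy = "C",
                          lx = 0, ly = 0, lz = 0, is_center = TRUE)
  cm <- voxelize(one, sc)
  expect_equal(sum(cm$grid), 1, tolerance = 0.02)
  m <- which(cm$grid == max(cm$grid), arr.ind = TRUE)
  expect_true(all(m[1, 1:3] %in% c(12, 13)))  # central voxels
})

test_that("cube maps are invariant under rigid motions of the structure", {
  st <- toy_complex(1)
  key <- attr(st, "patch_keys")[2]
  sc <- build_channel_scheme("element4")
  cm <- voxelize(extract_cube_atoms(st, key), sc)
  for (i in 1:3) {
    R <- random_rotation(100 + i)
    st2 <- transform_structure(st, R, c(3, -7, 2) * i)
    cm2 <- voxelize(extract_cube_atoms(st2, key), sc)
    expect_lt(max(abs(cm$grid - cm2$grid)), 1e-5)
  }
})

test_that("masking empties exactly the sphere", {
  st <- toy_complex(1)
  cube <- extract_cube_atoms(st, attr(st, "patch_keys")[1])
  m <- mask_sphere(cube, 5, "random", seed = 9)
  ctr <- m$mask$center
  d_kept <- sqrt((m$atoms$lx - ctr[1])^2 + (m$atoms$ly - ctr[2])^2 +
                   (m$atoms$lz - ctr[3])^2)
  expect_true(all(d_kept >= 5))
  d_all <- sqrt((cube$atoms$lx - ctr[1])^2 + (cube$atoms$ly - ctr[2])^2 +
                  (cube$atoms$lz - ctr[3])^2)
  expect_equal(nrow(m$atoms), sum(d_all >= 5))
  expect_gt(nrow(cube$atoms), nrow(m$atoms))  # at least the center atom

  # huge radius removes everything
  m2 <- mask_sphere(cube, 1e3)
  expect_equal(nrow(m2$atoms), 0)

  # determinism of the random center policy
  ma <- mask_sphere(cube, 5, "random", seed = 42)
  mb <- mask_sphere(cube, 5, "random", seed = 42)
  expect_identical(ma$atoms, mb$atoms)
  expect_identical(ma$mask$center, mb$mask$center)
})

test_that("the CB mask policy falls back to CA for glycine", {
  tmpl <- voxddg:::.center_residue_atoms("GLY")
  cube <- voxddg:::.as_cube(tmpl)
  m <- mask_sphere(cube, 2, "CB")
  ca <- tmpl[tmpl$elety == "CA", c("lx", "ly", "lz")]
  expect_equal(m$mask$center, as.numeric(ca))
})

test_that("interface cubes of a complex include partner atoms", {
  st <- toy_complex(1)
  sc <- build_channel_scheme("element4")
  cubes <- interface_cubes(st, sc)
  expect_setequal(names(cubes), attr(st, "patch_keys"))
  expect_true(all(vapply(cubes, function(cm) sum(cm$grid) > 5, logical(1))))
  f <- tempfile(fileext = ".rds")
  save_cubes(cubes, f)
  expect_equal(names(load_cubes(f)), names(cubes))
})
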