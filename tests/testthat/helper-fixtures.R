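# Shared fixtures kept deliberately small; heavier configurations are
# built inside the tests that need them.

toy_complex <- function(seed = 1) make_toy_complex(seed = seed)

tiny_trunk <- function(dropout = c(0, 0, 0)) {
  trunk_config(n_channels_in = 4, projector_dim = 3,
               conv_filters = c(3, 4, 4), conv_strides = c(2, 1, 1),
               pool = 1, n_voxels = 6, embed_dim = 7, fc2_dim = 5,
               dropout = dropout)
}

# One interface cube of the default toy complex, element channels.
toy_cube <- function(seed = 1, masked = FALSE) {
  st <- toy_complex(seed)
  key <- attr(st, "patch_keys")[1]
  cube <- extract_cube_atoms(st, key)
  if (masked) cube <- mask_sphere(cube, 5, "random", seed = seed)
  voxelize(cube, build_channel_scheme("element4"))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
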