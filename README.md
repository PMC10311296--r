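# voxddg

Local voxel models of protein–protein interfaces and binding-affinity
changes upon mutation.

## What it does

Most disease-related missense mutations fall on protein–protein
interfaces, and measuring how a mutation shifts a complex's binding free
energy (ΔΔG_Bind, kcal/mol) is slow and expensive. `voxddg` implements a
structure-based framework that deconstructs an interface into small,
locally oriented, residue-centered 3D environments and learns from them:

* **Representation.** Each interfacial residue gets a 24×24×24 cube of
  0.8 Å voxels, oriented by a local frame built from its backbone N, CA,
  C atoms. Heavy atoms of both partners deposit truncated-Gaussian
  densities into atom-type channels — either the full 167-channel
  (residue, heavy-atom) one-hot encoding or a 4-channel element encoding
  (C, N, O, S). The representation is rigid-motion invariant by
  construction.
* **Self-supervision.** A 5 Å sphere centered on a randomly chosen atom
  of the central residue is emptied and a 3D convolutional network is
  trained to recover the masked residue's identity, `P(y | env)` over
  the 20 amino acids, with inverse-frequency class weights.
* **ΔΔG prediction.** A Siamese network with strictly shared weights
  processes the wild-type and mutant cubes, merges the branches by
  subtraction (wild-type − mutant), concatenates five auxiliary
  descriptors of the site — conservation (T_JET), interface propensity
  (PC), circular variance (CV), structural region (SR, one-hot), and a
  mutation-specific substitution score (GEMME) — and outputs ΔΔG through
  one linear unit, trained on mean squared error. Ground truth derives
  from SKEMPI-style affinity tables via ΔG = RT ln K_d.
* **Interface anatomy.** Residues are classified by relative solvent
  accessibility in the bound and free states into interior, surface,
  support, core and rim (25% rASA threshold); support/core/rim are the
  interfacial residues that center cubes.
* **Harness.** Mutation-based k-fold and complex-based (no complex
  shared between train and test) splits, PCC/RMSE evaluation with
  stratified reporting, and deterministic synthetic fixtures so the
  entire pipeline runs and is tested offline.

The convolutional engine (im2col 3D convolutions, batch normalization,
average pooling, dropout, Adam, exact analytic gradients) is implemented
in the package itself with a small C++ gather/scatter kernel; no
deep-learning runtime is required.

## Worked example

```r
library(voxddg)

# a synthetic two-chain complex with a known 3-residue contact patch
st <- make_toy_complex(seed = 1)
acc <- assign_regions(compute_accessibility(st))
table(acc$region)
#> INT SUR SUP COR RIM
#>   0  10   0   0   6

ir <- interface_residues(acc)
ir$key
#> "A|6|" "A|7|" "A|8|" "B|6|" "B|7|" "B|8|"   # exactly the built patch

# a masked cube around one interfacial residue, element channels
cube  <- extract_cube_atoms(st, ir$key[1])
cube  <- mask_sphere(cube, radius = 5, center_policy = "random", seed = 4)
cm    <- voxelize(cube, build_channel_scheme("element4"))
sum(cm$grid)   # total density mass ~ number of atoms fully inside the cube

# ddG ground truth from dissociation constants (kcal/mol)
ddg_from_affinities(kd_wt = 1e-9, kd_mut = 1e-8, temperature = 298)
#> 1.363561   # = RT ln 10; positive destabilizes binding

# self-supervised masked-residue recovery on planted fixtures
fx  <- make_labeled_cubes(40, build_channel_scheme("element4"), seed = 11)
cfg <- small_trunk_config(4)
tr  <- train_ssdla(fx$cubes, fx$labels, cfg, epochs = 60, lr = 3e-3,
                   batch_size = 20, seed = 5)
P <- ssdla_forward(tr$model, fx$cubes)        # 20 x 40 probabilities
mean(rownames(P)[apply(P, 2, which.max)] == fx$labels)
#> 1            # the model recovers every planted label

# Siamese ddG recovery of a planted linear signal (alpha = 0.5, beta = 1)
dd <- make_synthetic_ddg(200, noise_sd = 0.3, seed = 21)
fit <- train_ddg(dd$wt_cubes[1:160], dd$mu_cubes[1:160],
                 dd$aux[1:160, ], dd$targets[1:160], cfg,
                 epochs = 30, lr = 3e-3, batch_size = 40, seed = 7)
pred <- ddg_forward(fit$model, dd$wt_cubes[161:200],
                    dd$mu_cubes[161:200], dd$aux[161:200, ])
evaluate_predictions(pred, dd$targets[161:200])$overall
#> $pcc  0.919   $rmse 0.863   $n 40
```

The held-out Pearson correlation of 0.92 on 40 unseen pairs shows the
Siamese model recovers both the cube-visible signal (atom-count
difference near the mutation site) and the auxiliary contribution from
under Gaussian noise.

A thin command-line wrapper over the same functions is installed at
`inst/cli/voxddg.R` (`regions`, `featurize`, `fixtures` subcommands).

## Documentation

The methods vignette (`vignettes/interface-cubes.Rmd`) describes the
model and its assumptions, every numerical choice (density kernel, voxel
ownership, mask boundary, SASA quadrature, burial tolerances), what the
synthetic generators do and do not emulate, and known limitations.
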