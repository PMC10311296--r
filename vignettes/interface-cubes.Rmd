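---
title: "Residue-centered voxel cubes of protein interfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-centered voxel cubes of protein interfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxddg)
```

## The model

`voxddg` treats a protein-protein interface not as one global object but
as a set of small, locally oriented 3D environments, one per interfacial
residue. Each environment is a cube of 24 x 24 x 24 voxels of side 0.8 A
(19.2 A per side) centered on the residue's C-alpha and oriented by a
local frame built from its backbone N, CA and C atoms. Every heavy atom of
either binding partner that falls inside the cube deposits a Gaussian
density into one channel of the cube; the channel encodes the atom's
identity. Because all coordinates are expressed in the residue-local
frame, the representation is invariant to rigid motions of the input
structure while preserving the relative orientation of its atoms — no
rotational data augmentation is needed.

Two learning tasks are built on this representation:

* **Masked-residue recovery (self-supervision).** A sphere of radius 5 A
  centered on a randomly chosen atom of the central residue is emptied,
  and a 3D convolutional network is trained to output `P(y | env)`, the
  probability of each of the 20 amino-acid types for the masked central
  residue. Masking a *fixed* volume, rather than the residue's own atoms,
  avoids leaking amino-acid-specific size or shape. The loss is a
  class-weighted categorical cross-entropy with weights inversely
  proportional to amino-acid frequency (`class_weights()`), which
  compensates the natural imbalance of residue types at interfaces.
* **Siamese ddG prediction.** For a point mutation, the cubes around the
  wild-type and the mutant residue are processed by two branches with
  strictly shared weights (one parameter object, not two synchronized
  copies). The branch outputs are merged by subtraction — wild-type minus
  mutant, a frozen convention — concatenated with auxiliary features, and
  mapped by a single linear unit to the predicted change in binding free
  energy (kcal/mol). The loss is the mean squared error. Because the head
  is linear in the branch difference, two exact identities hold and are
  tested: identical cubes contribute exactly zero, and
  `ddg(x, y) + ddg(y, x) = 2 ddg(x, x)`.

The shared trunk is: a 1 x 1 x 1 convolution projecting the per-voxel
channel vector to 20 dimensions, three 3 x 3 x 3 convolutions with batch
normalization, average pooling, and a flatten. The fully connected
subnetwork applies dropout of 40%, 20% and 10% to its input, first and
second layers. For the self-supervised head the layer sizes are (200, 20,
20) with a 20-way softmax; for the Siamese branches they are (200, 20).
The 200-dimensional activation of the first fully connected layer is the
residue *embedding* (`embed_cube()`), which downstream single-hidden-layer
classifiers (`embedding_classifier()`) map to categorical properties: the
seven physicochemical classes (ARO, CAST, PHOB, POS, POL-N, GLY, PRO) for
single cubes, or functional classes (antibody-antigen,
protease-inhibitor, TCR-pMHC) for embeddings averaged over an interface.

## Atom channels

The full one-hot encoding assigns one channel to every (residue type,
heavy-atom name) pair over the 20 standard amino acids: backbone N, CA,
C, O plus side-chain heavy atoms, no hydrogens, no terminal OXT. That
enumeration contains exactly 167 pairs, which fixes the channel
dimension. The ordering — alphabetical by 3-letter code, atoms in
topology order — is frozen and exportable as a plain-text table
(`write_channel_scheme()`) so stored cubes remain auditable. A reduced
4-channel scheme keyed on the chemical element (C, N, O, S) removes all
amino-acid-specific identity from the input and is the encoding used in
the desk-scale experiments below.

## Interface regions

A residue's relative solvent accessibility (rASA = ASA divided by the
residue type's theoretical maximum from Tien et al. 2013) is computed
twice: in the complex and in the free monomer obtained by deleting the
partner chains (rigid-body assumption, no relaxation). The five-region
scheme then classifies each residue with a 25% rASA threshold: buried
residues that lose no surface are *interior*, exposed ones *surface*;
residues that bury surface upon binding are *support* (already buried
when free), *core* (exposed when free, buried in the complex) or *rim*
(still exposed in the complex). The interfacial residues — the cube
centers — are exactly those in support, core or rim.

ASA itself is computed with a Shrake-Rupley rolling-probe quadrature
implemented in the package: probe 1.4 A, Bondi-type van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80 A), and a deterministic 256-point
Fibonacci sphere per atom. The region labels depend only on thresholded
rASA, so any consistent rolling-probe method gives the same labels; the
deterministic point set makes region counts reproducible. A burial
tolerance of 0.1 A^2 on raw ASA guards the interface test against
quadrature noise.

## Auxiliary features

Five descriptors accompany each mutation; four describe the wild-type
residue and one the specific substitution:

| feature | meaning | range / units | source |
|---|---|---|---|
| `t_jet` | evolutionary conservation | [0, 1] | JET-style file (`load_conservation()`) |
| `pc` | interface physicochemical propensity | log-odds scale | bundled table (`interface_propensity_reference()`) |
| `cv` | protrusion (circular variance) | [0, 1] | computed, 12 A cutoff |
| `sr` | structural region | 5-way one-hot | computed |
| `gemme` | substitution effect score | unbounded | GEMME-style file (`load_gemme()`) |

The encoded vector is `[t_jet, pc, cv, sr x 5, gemme]`, length 9. The
circular variance of a residue is `1 - ||mean unit vector to
neighbours||`, taken at the CA against heavy atoms of other residues
within 12 A; the cutoff is not fixed by the region scheme and 12 A is a
conventional neighbourhood radius for protrusion descriptors — it is an
argument, not a constant. The scalar features are min-max scaled over the
training set (`scale_aux()`); the stored ranges are applied unchanged to
test data. Ablation configurations (`SR`, `SR-Tjet`, `SR-GEMME`, `All`)
zero the excluded scalar slots while keeping the vector length fixed, so
one trained architecture serves all configurations. Conservation and
substitution scores are *parsed, never computed*: both derive from
multiple sequence alignments and are produced by external tools.

## Numerical choices

* **Density kernel.** Each atom contributes a separable Gaussian with
  sd = 0.8 A (the voxel side), truncated at 2 sd per axis and
  renormalized; per-voxel values are the analytic integral of the kernel
  over the voxel box (differences of normal CDFs), not a point sample.
  With this construction an atom whose kernel support lies inside the
  grid deposits total mass exactly 1, which the tests verify to 2%; the
  kernel sd and truncation are arguments of `voxelize()`.
* **Voxel ownership.** Voxel `i` along an axis covers
  `[-9.6 + 0.8 i, -9.6 + 0.8 (i + 1))` — half-open, lower-inclusive — so
  no coordinate belongs to two voxels.
* **Mask boundary.** An atom at distance exactly `r` from the mask center
  is kept; only strictly interior atoms are removed. The mask removes
  atoms of *any* chain, including the partner: the sphere becomes truly
  empty space. The random center is drawn uniformly over the central
  residue's heavy atoms with an explicit seed, so training sets are
  reproducible.
* **Local frame.** origin = CA, `e1 = unit(N - CA)`,
  `e3 = unit(e1 x (C - CA))`, `e2 = e3 x e1`. Only backbone atoms enter,
  so the frame exists for glycine; orthonormality, right-handedness and
  rigid-motion equivariance are construction guarantees and are tested.
  Collinear backbone atoms raise an error; residues missing a backbone
  atom are skipped with a warning.
* **Degenerate inputs.** Empty cubes voxelize to all-zero maps;
  non-contacting partners yield an empty interface with a warning rather
  than an error; zero amino-acid frequencies make `class_weights()` fail
  loudly, as they signal a degenerate training set.
* **ddG ground truth.** `dG = R T ln(Kd)` with
  `R = 1.9872e-3 kcal/(mol K)`; missing or unparseable temperatures
  default to 298 K. Replicate measurements of the same mutation are
  aggregated by the median, a robust choice given that replicate
  disagreements between laboratories are common; the policy is an
  argument of nothing — it is applied uniformly and logged per row.

## Network engine

No deep-learning runtime is part of the package's dependency set; the
convolutional engine is implemented in the package itself. Activations
between convolutional layers are stored as a `channels x (voxels *
samples)` matrix; convolutions are evaluated as an im2col gather (a small
C++ routine) followed by one BLAS matrix product, and the backward passes
are exact analytic gradients — the test suite checks every parameter
block against numerical differentiation to 1e-5 relative error. Adam is
the optimizer throughout, with the documented learning rates (1e-4 for
self-supervised pre-training, 1e-3 for fine-tuning) as defaults;
training is fully seeded (initialization, shuffling, dropout) and
bitwise reproducible on one device.

The filter counts, kernel sizes and strides of the three convolutions
are free hyperparameters (`trunk_config()`): the documented default is
stride-1 convolutions with filters (32, 64, 128) followed by average
pooling of the grid to 3 x 3 x 3. The desk-scale configuration used in
the examples and tests (`small_trunk_config()`) instead coarsens the
grid with stride-2 convolutions (filters 8, 12, 16, no terminal
pooling), which reaches the same 3 x 3 x 3 terminal grid with far less
compute; on one CPU core it trains the 40-cube recovery experiment in
about a minute and the 200-pair ddG experiment in a few minutes. When
the Siamese model is initialized from a pre-trained masked-residue
model, the trunk and the first fully connected layer are transferred and
the remaining layers are fresh.

## What the synthetic generators emulate

All tests run offline on synthetic inputs with known ground truth:

* `make_toy_complex()` builds two idealized chains whose last residues
  (given long side chains) face each other across a 9 A gap, insulated
  from the rest of the chain by a 12 A offset, so that *exactly* the
  constructed patch buries surface upon complexation. It is emitted as a
  valid PDB and re-parses losslessly.
* `make_labeled_cubes()` plants, for each amino-acid label, a
  distinctive spherical shell of atoms at 7.8 A — outside the reach of
  any 5 A mask placed on the central residue — whose atom count and
  element pattern encode the class. A model that recovers these labels
  demonstrates that the pipeline (masking, voxelization, network,
  training) transmits and learns local-environment signal.
* `make_synthetic_ddg()` plants a linear ground truth: the target is
  `alpha x (atom-count difference near the center) + beta x gemme +
  noise` with `alpha = 0.5`, `beta = 1` and Gaussian noise of sd 0.3
  kcal/mol — noise comparable to the experimental uncertainty of binding
  assays. Held-out correlation above 0.8 on 200 pairs shows the Siamese
  architecture recovers both the cube-visible and the auxiliary part of
  the signal.

What passing these tests does *not* show: that the trained models
transfer to real complexes. Real interfaces have correlated side-chain
packing, conformational variability upon mutation, and amino-acid
composition biases that the generators deliberately do not model;
obtaining competitive accuracy on experimental mutation panels requires
curated complex structures, modelled mutant conformations and long
training runs, all outside the package's test scope. The problem
sizes above (40 cubes, 200 pairs, reduced trunk) were chosen once as the
smallest sets on which the planted signals are comfortably learnable.

## Known limitations

* Two-partner complexes only; no multi-chain-group decomposition.
* Single-point mutations; multi-point effects are not modelled.
* PDB input only (no mmCIF); no hydrogen placement or structure repair;
  the first alternate location (by occupancy) and model 1 are used.
* Conservation and substitution scores must be precomputed externally.
* Cube containers are persisted as RDS with embedded metadata
  (`save_cubes()`); the format is internal to R sessions.
* The bundled interface-propensity table is a documented default, not a
  canonical constant; studies with their own scale should pass it
  explicitly.
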