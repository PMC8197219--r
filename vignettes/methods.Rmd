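---
title: "Voxel-based DNA-binding-site prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based DNA-binding-site prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxbind)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the parameters that matter, and the design
choices made where the method leaves room. Code chunks are illustrative and
not evaluated at build time; every empirical number quoted here is computed
by the test suite or by `scripts/acceptance.R`, nowhere else.

## The problem and the modelling idea

Protein–DNA recognition is governed by the local chemical texture of the
protein surface, not only by which residues are present. The pipeline
therefore discards sequence entirely and represents a protein as a 3D image:
a 1-Å voxel grid whose channels encode *what kind of atom* sits where on the
solvent-accessible surface. Binding-site prediction becomes semantic
segmentation — label every voxel with the probability that it belongs to the
DNA-binding region — which a fully convolutional network can do for inputs
of any size, with no cropping or resizing of the structure.

Two design commitments follow. First, the protein is always featurized *in
isolation*: DNA atoms are excluded from the SASA calculation, from the atom
channels, and from the candidate regions, so the network can never see its
own answer. DNA enters only through the training labels. Second, everything
downstream of parsing is deterministic given a seed: surface points are a
golden-spiral lattice rather than random samples, rotations are the exact
cubic group, k-means is seeded, and training order is a seeded shuffle.

## Surface and atom types

SASA uses Shrake–Rupley: each atom's sphere is inflated by the probe radius
(default 1.4 Å, water) and sampled at `n_sphere_points` (default 960)
deterministic golden-spiral points; the accessible fraction times
`4*pi*(r+probe)^2` is the area. A lone carbon therefore scores exactly
`4*pi*3.1^2 = 120.76` Å², which the tests check against a 1 % tolerance, and
independent Monte-Carlo surface integration agrees within 2 % on
multi-sphere fixtures. The van der Waals radii are a small explicit table
(C 1.7, N 1.55, O 1.52, S 1.8, P 1.8, metals 2.0 Å) and configurable; an
element without a radius is an error rather than a guess. An atom is
"surface" when its SASA is strictly positive — the most inclusive reading;
the threshold is a parameter (`surface_threshold`, Å²) for users who want a
stricter shell.

Surface atoms are assigned one of 16 codes with a three-symbol grammar:
element (C/N/O/S), context (`2` sp2, `3` sp3, `R` aromatic ring, `C`
conjugated/resonating), and electrostatics (`N` nonpolar, `P` polar, `V`
variable, `C` charged), plus `PHO` and `MET` for phosphorus and metals.
The shipped residue × atom table applies the grammar mechanically: backbone
N/C′/O are conjugated-polar (`NCP`/`CCP`/`OCP`), CA is `C3P`, aliphatic
side-chain carbons are `C3N`, aromatic carbons are `CRP` when adjacent to a
polar ring substituent and `CRN` otherwise, carboxylates are `OCC`,
hydroxyls `O3P`, thioethers/thiols `S3N`, the His and Trp ring nitrogens
`NRV` (their protonation is ambient-dependent), and the Arg guanidinium
nitrogens `NCC`. Two judgement calls are worth flagging: CA could be argued
nonpolar (`C3N`) — we follow the polar reading since it bonds two backbone
heteroatom groups; and `C2P` ends up unused by the 20 standard residues
under this grammar, though it remains in the closed code set. The table is
an editable TSV (`inst/extdata/atom_types.tsv`); disagreements can be fixed
without touching code, and `screen_complex()` rejects complexes containing
atoms the table cannot type (including modified residues such as MSE)
rather than mistyping them.

## Grid, labels, rotations

The grid covers the protein bounding box plus `padding` (default 3 Å) on
every side at fixed 1-Å resolution; voxel centres sit at half-integer
offsets from the origin and the world-to-index map is `floor`-based with
half-open cells. Each protein atom writes a one-hot on its nearest voxel
over 17 channels (16 types plus a buried-atom sentinel — buried atoms carry
shape information even without a surface chemistry). When two atoms fall in
one voxel the atom nearest the voxel centre wins, ties to the lower serial;
the rule is rotation-equivariant, which the tests exploit.

A voxel is a *binding voxel* iff some protein atom P and DNA atom D satisfy
all three of: d(voxel, P) ≤ 6 Å, d(voxel, D) ≤ 6 Å, d(P, D) ≤ 6 Å, with
voxel distances measured from the centre. The triple rule, rather than the
looser "within 6 Å of the protein–DNA midzone" phrasing, is implemented as
definitive; the production path marks ball intersections per qualifying
(P, D) pair, and tests compare it voxel-for-voxel against an exhaustive
per-voxel scan. The 6-Å cutoff is the permissive end of the conventions in
use for binding-residue definitions; mask positivity is monotone in it.

Augmentation uses the 24 proper rotations of the cube — signed permutation
matrices with determinant +1 — applied as axis permutations/reversals so
the voxel multiset is exactly preserved. Grid origins are re-anchored so
that rotating coordinates and then voxelizing equals voxelizing and then
rotating (the tests verify this exactly on half-integer fixtures, which
keep atoms away from cell boundaries where the half-open convention would
flip).

## Network and training

The architecture is a UNET over dense blocks. A dense block is four 3×3×3
convolutions, each followed by MISH (`x*tanh(softplus(x))`; smooth,
non-monotone near zero, identity-like for large inputs); layer *k* receives
the block input concatenated with all previous layer outputs — so with
growth rate *g* its input has `C_in + (k-1)*g` channels — and the block
emits the concatenation of its four layer outputs (`4g` channels). The
encoder stacks `n_levels` such blocks (default 3) with 2× average pooling
between scales; the decoder mirrors them with nearest-neighbour
up-sampling and skip concatenation; a 1×1×1 sigmoid head gives one output
channel. Inputs are zero-padded internally to a pool-compatible size and
cropped back, so output spatial shape always equals input shape. Depth,
growth, kernel and pooling operator are config-exposed; average pooling was
chosen over max for its smooth, exactly-invertible gradient, and the block
output convention (layer outputs only, without the block input) keeps
channel counts flat across the UNET — both are places where reasonable
implementations differ.

The loss is mean per-voxel binary cross-entropy with a 1e-7 clamp. A
constant p = 0.5 predictor scores exactly `ln 2 = 0.69315` on any label
set — the uninformative baseline against which training progress is read.
Optimization is Adam; the default "ranger" setting wraps it in LookAhead
(sync every 5 steps, interpolation 0.5), approximating the AdamW+LookAhead
combination as a training contract rather than a named dependency. The
forward/backward passes are hand-written over a small op set with the
3×3×3 convolution in compiled code; the backward pass is verified against
finite differences to ~1e-8 relative error. Complexes are split 9:1 by
complex identifier (all rotations stay together, so augmented copies can
never leak across the split); complexes whose grids exceed
`max_grid_voxels` go to validation, mirroring the memory-bound routing of
large complexes. The trained model returned is the best-validation
checkpoint.

## Binarization and evaluation

The heat map is continuous; applications need a binary call. A fixed
threshold ignores spatial coherence, so the binarizer clusters instead:
candidate voxels (within 6 Å of a surface atom — the prediction's
meaningful support; clustering bulk vacuum would let empty space dominate
the geometry) become (x, y, z, score) points, each dimension standardized,
the score then inflated 5× to bias clusters toward score structure. Round
one forms `ceiling(n_atoms/1000)` clusters (k-means++-style seeded
`stats::kmeans`, 10 restarts); round two clusters the per-cluster mean
scores into two groups, and the higher-mean group becomes the binding
region. Degenerate cases are explicit: no candidates or zero score variance
give an all-zero call; a single first-round cluster is binding iff its mean
exceeds 0.5; when the first round yields no more clusters than the second
round requests, each cluster is trivially its own group and the top one is
taken. Standardization makes the call invariant to uniform score shifts.

Evaluation is per-voxel. Counts and the derived accuracy, sensitivity,
specificity, precision and MCC (zero by convention when a marginal
vanishes) are taken over an evaluation region that defaults to the voxels
within 6 Å of any protein atom: counting far-field vacuum as negatives
would inflate specificity arbitrarily with padding. The whole-grid region
remains available as an option for the literal per-grid reading. AUC uses
the Mann–Whitney rank statistic with midranks; tests pin it to trapezoidal
ROC integration at 1e-9 and to an established ROC package.

## What the synthetic data does and does not show

`generate_complex()` builds a compact protein coil (3.8-Å CA steps, full
standard heavy-atom names scattered near each CA) against a twin-rail DNA
of standard-named pseudo-nucleotides, placed so the minimum protein–DNA
separation hits a requested contact distance within ±0.5 Å. Geometry is
idealized, not physical: bond lengths, sterics and base pairing are wrong
on purpose. These fixtures prove that parsing, screening, SASA, typing,
voxelization, labelling, rotation, archiving, training mechanics,
binarization and scoring compose correctly and deterministically — they
cannot show that the network recognizes real DNA-binding chemistry,
because the fixtures contain none. Accordingly, the end-to-end synthetic
run in the acceptance script reports chance-level held-out AUC/MCC, and
that is the honest expectation; demonstrated learning comes from the
planted-pattern task (`generate_planted_task()`), where a motif channel
must be dilated into its Chebyshev-2 neighbourhood — a localized,
convolution-sized mapping a 3-level growth-8 UNET drives from the ln 2
baseline to below `0.1*ln 2` held-out BCE within 300 single-sample steps.

## Problem sizes and numerical choices

Defaults used by the tests and the acceptance script: planted-pattern grids
12³ with 17 channels, 40 training / 8 held-out samples, 300 steps at
learning rate 4e-3; synthetic complexes of 5–10 residues and 2–4
nucleotides per strand; 20 random 50-atom fixtures for the labelling
oracle; 960 surface points per atom. These sizes were chosen so every
claim is recomputable on a single CPU in minutes while still exercising
multi-scale convolution, and they are stated here as the package's
reference conditions. Other numerical choices: loss clamp 1e-7; He-style
weight initialization with a zero head bias so the initial output sits near
p = 0.5 (initial BCE ≈ ln 2); Adam β = (0.9, 0.999), ε = 1e-8; k-means
restarts 10.

## Known limitations

- The atom-type table is a rule-based reconstruction; individual
  assignments beyond the documented exemplars may differ from other
  implementations of the same grammar. It is data, not code, precisely so
  it can be corrected.
- Shrake–Rupley with 960 points quantizes small areas (~0.13 Å² per point
  for carbon); `surface_threshold = 0` therefore means "at least one free
  point".
- The binarizer assumes one dominant high-score region; multi-patch
  binding surfaces can be merged or split depending on the atom-count-driven
  cluster budget.
- mmCIF input, automated structure retrieval, arbitrary-angle augmentation
  and per-residue metric aggregation are out of scope.
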