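---
title: "Predicting antibody viscosity from surface electrostatics: models and methods"
author: "espvisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibody viscosity from surface electrostatics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Therapeutic monoclonal antibodies are formulated at high concentration
(around 150 mg/mL) for subcutaneous delivery, where some molecules become
viscous enough to block manufacturing and administration. Measuring
viscosity rheometrically needs >100 mg of purified protein, so experimental
datasets are tiny — a few dozen molecules — which has kept deep learning out
of this problem. The approach implemented here gets around the small-n limit
with a biophysically constrained input: the *only* thing the model sees is
the electrostatic potential (ESP) on a thin shell just outside the molecular
surface of the antibody variable region (Fv). Surface charge patches,
especially clustered negative charge, are the dominant physical driver of
concentrated-solution viscosity, so restricting the network to the ESP
surface prevents it from memorizing irrelevant structural detail.

`espvisc` implements the full pipeline: structure in, voxelized ESP surface
shell, a small 3D convolutional network trained with rotation augmentation
and cross-validation ensembling, integrated-gradients interpretation of the
trained models, two classical baselines, evaluation machinery, and a
synthetic-structure generator so that every stage is testable end to end
without any proprietary data.

## Input representation

**Geometry.** Coordinates are translated so the center of mass sits at the
Cartesian origin (`canonicalize()`). Fields are sampled on a cubic grid from
−36 to +36 Å per axis at 0.75 Å spacing (97 points per axis;
`gridSpec()`).

**Surface.** The solvent-excluded (Connolly-type) volume is built directly
on the grid by a two-pass morphological construction (`computeSES()`): mark
all voxels within (atom radius + probe radius) of an atom center, then erode
away every voxel a probe sphere (radius 1.4 Å) can reach from outside.
The erosion uses an exact Euclidean distance transform, so on small grids
the result is voxel-identical to brute-force probe placement (this is
asserted in the tests). An analytic triangulated surface would add nothing
here: the downstream consumer is the voxel grid itself.

**Shell.** The network input keeps the potential only on exterior voxels
within 2 Å of the surface (`computeShell()`); voxels inside the molecule
(where the continuum ESP is ill-defined) and voxels farther out are exactly
zero. Shell membership uses the voxel-center distance to the nearest
interior voxel; the alternative (distance to an analytic surface) differs by
less than a voxel and the stated shell thickness is itself approximate.

**Electrostatics.** `solveESP()` solves the linearized Poisson–Boltzmann
equation by finite differences: 7-point stencil, harmonic-mean face
dielectrics from the interior/exterior map (inner dielectric 1, outer 80),
trilinear charge spreading, Dirichlet boundary values from the
Debye–Hückel sum, SOR iteration to a 1e-5 relative residual (at most
10,000 sweeps). Potentials are reported in kT/e at 298 K; the single
conversion constant (e²/ε₀kT = 7046.2 Å) is documented in the source. The
default ionic strength is 0 (κ = 0) since the reference calculation's salt
treatment is unknown; `ionicStrength` is exposed in molar units. A direct
screened-Coulomb solver (`solveDebye()`) provides a uniform-dielectric
fallback and the boundary condition, and the two agree within 5% away from
charges — a tested invariant.

**Charges and radii.** Rather than depend on a proprietary force field, a
bundled minimal parameter table localizes formal charges where the sign
structure of the ESP needs them: −1 on Asp/Glu carboxylates, +1 on the Lys
amine and Arg guanidine group, small self-cancelling partial charges on
backbone N/CA/C/O, zero elsewhere, with per-element van der Waals radii
(united-atom radii when a model has no hydrogens). Histidine and the chain
termini are neutral by default — at formulation pH (~5.8–6.0) His is
borderline, so both are configurable (`assignParameters()`).

**Hydrophobicity channels.** The alternative two-channel representation
(`buildEisenbergInput()`) separates hydrophobic and hydrophilic residues by
the sign of their Eisenberg scale value, gives each atom a unit-height
Gaussian whose width is 3×|scale| of its parent residue (density falls to
e⁻¹ at that radius — the height is fixed by convention, the width
convention is ours), sums the Gaussians on the grid and applies the same
shell mask. The combined representation stacks ESP + both Eisenberg
channels into three channels.

**Padding.** 97 physical points per axis are centered in a 128³ zero-padded
cube. Six pooling halvings then give a 2³ spatial map with 128 filters —
a 1024-long flattened feature vector. This padded size is an inference
(97 is not divisible by 2⁶); it is the unique power of two consistent with
the network arithmetic.

## Network and training protocol

The regression network (`buildNet()`) is six blocks of
[3×3×3 convolution (same padding) → ReLU → 2× max pooling], starting at 4
filters and doubling per block (4…128), followed by flattening, dropout
(rate 0.05) and a single linear output node. Weights are Glorot-uniform
initialized. Training (`trainFold()`) minimizes Huber loss (δ = 1) with
Adam at a fixed learning rate of 1e-5, batch size 1, for 2000 epochs;
validation loss is evaluated every epoch and the checkpoint with the lowest
validation loss within the final 50 epochs is kept (ties go to the later
epoch). With ~3×10⁵ parameters and a few dozen training molecules the model
is massively over-parameterized; the restricted input representation, the
augmentation and the ensembling are what make this trainable.

Because no deep-learning framework for R is assumed, the forward pass,
backpropagation, Adam and the training loop are implemented in C++ inside
the package, single-threaded with an own RNG, so that training and inference
are bit-reproducible given a seed.

**Augmentation.** Every training structure is rotated by 10 independent
uniform random rotations (quaternion sampling) about its center of mass and
each rotated copy is featurized separately (`randomRotations()`). This both
multiplies the training data and averages out the sensitivity of grid-based
ESP values to the charge–voxel alignment.

**Ensembling.** `trainCVEnsemble()` splits structures (never individual
rotations) into 10 cross-validation folds and trains one network per fold.
At inference (`predictViscosity()`) 10 freshly rotated copies of the query
are run through all 10 models — 100 predictions whose mean, after inverse
target transform, is the reported viscosity. The leave-one-out protocol
(`loocvProtocol()`) wraps this: each molecule of a 21-member set is held out
once while the other 20 plus all 38 of the second set (58 structures) are
trained on.

**Target transform.** The network regresses log10(η/cP) by default and
predictions are inverse-transformed. The choice is ours: viscosity
distributions are strongly right-skewed and a Huber loss on raw cP would be
dominated by the few-hundred-cP tail. `targetTransform = "raw"` is
available.

## Interpretation

`integratedGradients()` attributes the prediction to input voxels along the
straight path from an all-zero baseline, with a midpoint Riemann rule
(default 128 steps). Scores are exactly zero at masked voxels and satisfy
the completeness identity to well under 1% at the default step count (a
ReLU network is piecewise linear, so the path integral converges quickly).
A positive score marks a voxel that pushes the predicted viscosity up.

The significance threshold (`poolSignificance()`) is the population standard
deviation of all nonzero attribution scores pooled over a test set.
Voxels above threshold are grouped into **patches**
(`findPatches()`): connected components, per sign, linking voxels within
1.5 Å (twice the production grid spacing). Patch composition is reported
two ways: by biophysical category of the nearest protein heavy atom —
Asp/Glu sidechain > H-bond acceptor (any other oxygen) > aromatic sidechain
(His/Phe/Tyr/Trp) > H-bond donor (nitrogens, the Lys amine, the Arg
guanidine) > lipophilic carbon, in that priority — and by Fv segment
(framework or CDR loop via Chothia ranges, bundled as L1 24–34, L2 50–56,
L3 89–97, H1 26–32, H2 52–56, H3 95–102 and overridable).

`carboxylateAttribution()` quantifies the charge-neutralization effect:
Asp/Glu residues are split into *proximal* (carboxylate within 3.5 Å of a
cation center — Lys NZ or the Arg guanidine) and *distal* (at least 5 Å;
the 3.5–5 Å band is excluded), a grid point is associated with a
carboxylate when its nearest heavy atom is one of the three carboxyl atoms
and it lies within 4 Å of one of them, and the mean attribution of each set
is returned.

For per-molecule maps from a whole ensemble, `ensembleAttribution()`
computes one attribution grid per (model × rotation), maps each back to the
unrotated frame by the inverse rotation with nearest-voxel resampling, and
averages. How the reference pipeline combined its 100 attribution replicas
is not fully specified; this averaging convention is our choice and is kept
symmetric with the prediction ensemble.

## Baselines

`sharmaFeatures()`/`fitSharma()` re-implement the classic three-feature
sequence model: Fv net charge and the VL×VH charge-symmetry product from
Henderson–Hasselbalch fractional charges (bundled pKa table: D 3.65, E 4.25,
H 6.0, K 10.53, R 12.48; termini optional), plus a hydrophobicity index
(sum of positive Eisenberg values over |sum of negative values|), fitted by
ordinary least squares to (log) viscosity. The original published
coefficients were calibrated at 180 mg/mL on a different chemical space and
are deliberately not reproduced; the model is refit per training set.

`scmScore()` is a structure-based clustered-negative-charge score: for every
solvent-exposed heavy atom (≥10% of 92 probe-sphere points outside the SES),
sum the partial charges within 10 Å and accumulate |min(0, sum)|. Larger
scores mean larger or denser negative surface patches. The exposure
threshold and radius are exposed; the exact published constants differ
between implementations, so these defaults are package choices.

## Evaluation

`regressionMetrics()` reports Spearman rank correlation (average ranks) and
R² computed on the log10 scale by default (matching the training target;
raw-scale option provided). `rocAnalysis()` sweeps all prediction
thresholds at the 20 cP class boundary (viscous ≥ 20 cP), computes the
trapezoid AUC — identical to the Mann–Whitney pairwise concordance, a
tested identity — and selects the optimal operating point as the threshold
closest to the (FPR 0, TPR 1) corner, ties to the higher TPR; Youden's J is
available since the reference convention is not stated. Confidence
intervals are percentile bootstrap over 500 paired resamples
(`bootstrapCI()`), seeded; resamples with undefined metrics are skipped and
counted. `nullModelAccuracy()` gives the majority-class accuracy that any
classifier must beat on an imbalanced set.

## The synthetic test system

`makeToyStructure()` builds a compact pseudo-protein: residues on a
Fibonacci sphere (default 40 residues, 6 Å core radius) with neutral
Ala/Ser scaffolds and radially oriented sidechains, where a *patch
specification* converts all residues within an angular cap into Asp/Glu
(negative patch) or Lys/Arg (positive). Atom names follow PDB conventions
so parameter assignment, surface computation and nearest-atom
classification run unchanged. `makeLabeledDataset()` sweeps the patch
angular radius from 0° to 75° across the set and generates labels as

log10(η/cP) = 0.3 + 0.0025 × A⁻ + N(0, 0.1),

where A⁻ is the *negative-patch electrostatic area*: the number of shell
voxels with potential below −0.5 kT/e, computed by the package's own
surface/ESP pipeline at desk scale. The slope and intercept were fixed once
from the geometric range of A⁻ (roughly 90–710 voxels across the sweep) so
that labels span ~3–120 cP and straddle the 20 cP class boundary, i.e. a
realistic viscosity spread; the 0.1 log-unit noise (~25% multiplicative)
mimics inter-assay variability.

What the generator emulates: a monotone causal link from clustered negative
surface charge to log viscosity, with noise, at sizes where the whole
pipeline runs in minutes. What it does not emulate: antibody geometry,
sequence realism, backbone chemistry, conformational variability, or the
magnitude of any published accuracy. Passing the recovery test therefore
demonstrates that the pipeline can learn the intended signal class from few
examples — not that it reproduces real-antibody performance, which requires
real structures and the full-scale configuration.

**Desk-scale profile.** Tests and the acceptance script use
`deskPreset()`: ±12 Å grid at 1.5 Å spacing (17³ physical) padded to 32³,
five convolution blocks (32 is not divisible by 2⁶, so one block is
dropped; the flattened vector is 64-long), learning rate 1e-3 over 200
epochs, 3-fold cross-validation, 2 rotations per structure. The larger
learning rate is deliberate: a 30× shorter schedule on a ~30× smaller input
needs a proportionally larger step, and 1e-3 is the standard Adam default.
The production profile (`paperPreset()`) keeps the full 128³ grid, six
blocks, learning rate 1e-5 and 2000 epochs.

## Numerical choices and degenerate inputs

* SES interior uses the strict inequality (distance-to-outside > probe) in
  exact squared voxel units, and the brute-force oracle uses the same
  convention, so the comparison is exact, not tolerance-based.
* SOR uses ω = 2/(1 + sin(π/n)); convergence failure is an error carrying
  the residual, never a silent return.
* Atoms outside the grid extent are a hard error naming the atom — silent
  clipping would corrupt the ESP.
* Point-charge singularities in the screened-Coulomb sum are clamped at
  half a voxel.
* Checkpoint ties inside the selection window go to the later epoch; OOP
  ties go to the higher TPR; patch ordering ties break by sign then lowest
  voxel index.
* An empty structure, an all-exterior occupancy, a test set with a single
  class, an all-zero attribution map, and a rank-deficient baseline design
  each raise informative errors rather than returning defaults.

## Limitations

* No homology modeling: inputs are existing PDB structures (or synthetic
  stand-ins). Protonation states are fixed by the parameter table.
* The PB solver is linearized, single-grid SOR; no nonlinear PB, explicit
  ions or multigrid. At 0.75 Å spacing and κ = 0 this is accurate to a few
  percent against closed forms, which is sufficient for the shell
  representation.
* Attribution averaging across rotations uses nearest-voxel resampling;
  sub-voxel smearing at patch boundaries is possible.
* Published accuracies on the real antibody sets are out of reach without
  the original structures and modeling pipeline; the package's quantitative
  guarantees are the protocol counts, closed-form agreements and the
  synthetic recovery experiment that the test suite and
  `scripts/acceptance.R` actually compute.
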