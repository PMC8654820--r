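---
title: "BoxCC methods: density model, bCC, and the synthetic training pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BoxCC methods: density model, bCC, and the synthetic training pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoxCC)
```

This vignette records the physical model, the numerical conventions, and
the deliberate simplifications behind BoxCC, so that every number the
package produces can be traced to an explicit choice.

## 1. The density model

### Atomic density

Each atom's electron density is an isotropic Gaussian sum derived from the
standard IT92 scattering-factor parameterization. The tabulated form
$f(s) = \sum_{i=1}^{4} a_i e^{-b_i s^2} + c$ is carried into real space by
folding the constant $c$ into a fifth Gaussian with $b_5 = 0$, giving

$$\rho(r) = \sum_{i=1}^{5} a_i \left(\frac{4\pi}{b_i + B}\right)^{3/2}
  e^{-4\pi^2 r^2 / (b_i + B)},$$

where $B$ is the isotropic displacement parameter. The $b_5 = 0$ term has
zero intrinsic width, so the package requires $B > 0$ everywhere — no real
workflow is affected, because calculated density is always synthesized
after resetting $B$ to 2 Å². The parameterization integrates to the
electron count:

```{r}
tab <- scatteringTable()
f <- function(r) 4 * pi * r^2 * atomicDensity("O", r, bIso = 15, table = tab)
integrate(f, 0, 12, rel.tol = 1e-10)$value   # electrons in an oxygen
```

### Structure factors and maps

Structure factors are computed by direct P1 summation,
$F(\mathbf{h}) = \sum_j occ_j\, f_j(s)\, e^{2\pi i\,\mathbf{h}\cdot\mathbf{x}_j}$,
over all Miller indices inside the resolution sphere $d \ge d_{\min}$;
$F(000)$ equals the model electron count, and Friedel symmetry
$F(-\mathbf{h}) = \overline{F(\mathbf{h})}$ holds by construction. Map
synthesis places the coefficients on a reciprocal grid and inverse-FFTs,
normalizing by the cell volume. The test suite pins the two routes
together: direct real-space summation and Fourier synthesis agree to
correlation > 0.999 on a dipeptide fixture, and Parseval's identity
$\frac{V}{n}\sum \rho^2 = \frac{1}{V}\sum |F|^2$ holds to $10^{-6}$.

Grid choices: `gridDimsForDmin()` yields 3 samples per $d_{\min}$ (a 1.5×
oversampling of the Nyquist minimum of 2), with even dimensions for FFT
efficiency; `mapFromReflections()` refuses grids below Nyquist rather than
silently aliasing.

### Simulated observed maps

`simulateObservedMap()` emulates an experimental 2mFo-DFc-like map without
refinement: per-atom B factors follow a base-plus-exposure profile
(B = 15 + 25 × normalized distance from the molecular centroid, so surface
atoms blur more), structure factors are truncated at the stated resolution,
complex Gaussian noise of a stated relative magnitude is added
(Friedel-symmetrically, leaving $F(000)$ untouched), and the map is
synthesized by FFT. What this deliberately omits: solvent/bulk-water
contribution, measurement-error models beyond white noise, and the partial
re-fitting of a model to truncated data that refinement programs perform.
The last omission matters when comparing against published per-resolution
numbers and is the main known fidelity gap of the resolution series.

## 2. The metric

`bcc()` is the Pearson correlation over all voxels of two equally shaped
boxes. Boxes are extracted by `extractBox()` on a residue-centroid-centered
cubic lattice (default edge 12 Å, spacing 0.5 Å → 24³ voxels), sampling the
periodic map by trilinear interpolation in fractional space; interpolation
is exact for affine fields, which the acceptance suite asserts. A
zero-variance box raises a `degenerateBoxError` instead of returning a
value, so empty solvent regions can never silently corrupt scores or
training labels.

The scoring pipeline (`perResidueBcc()`) strips waters, hetero compounds,
hydrogens and alternate conformers (keeping the highest-occupancy
conformer), resets B to 2 Å², synthesizes the calculated map once for the
whole cell, and correlates observed against calculated boxes per residue.
B = 2 rather than refined B values makes the metric score *coordinates
only* — a misplaced atom cannot hide behind an inflated B factor.

Two properties define the metric's character, and both are asserted
exactly in the acceptance tests:

* **Model-bias independence.** bCC compares the model against a fixed
  high-resolution map; the (possibly model-phased) map that accompanies
  the model plays no role. RSCC on the same fixtures is inflated by model
  phases: against a map built from true amplitudes and wrong-model phases,
  RSCC exceeds its value against the true-phased map at every resolution,
  and the inflation varies severalfold across 1.5–3.5 Å. The raw RSCC
  still *decreases* with truncation (blurring dominates), so the
  inflation is measured as the biased-minus-unbiased difference.
* **Single-atom insensitivity.** In a 12 Å box inside a packed protein
  environment, one water oxygen carries well under 1 % of the box
  variance; removing it from the calculated channel changes bCC by
  < 1 % (`singleAtomContribution()`, acceptance target t1).

### Numerical choice: band-limited calculated maps at B = 2

At B = 2 Å² an atomic peak has σ ≈ 0.16 Å, far sharper than a 0.5 Å grid
can represent; sampling the analytic density directly on such a grid
aliases. For single-atom difference experiments (where the aliasing noise
competes with a small signal), `singleAtomContribution()` therefore offers
`dMinCalc`: the calculated maps are synthesized from structure factors
band-limited at the grid's Nyquist resolution (1.0 Å for 0.5 Å spacing),
which is the conventional crystallographic calculated map. Bulk scoring
keeps the direct route, where the aliasing affects both channels alike and
cancels in the correlation.

## 3. The learning pipeline

Descriptors are five-channel voxel boxes: the observed map plus the
calculated density of the model's C, N, O and S atoms separately (the
channel sum reproduces the full calculated box exactly, a tested
linearity). Labels (`bCC_act`) are computed end-to-end through the same
public scoring operations against the finest-resolution map of the correct
structure. Archives store records per amino-acid type with a manifest
carrying counts, the label histogram, generator provenance and MD5 content
hashes; regeneration from (config, seed) is bit-identical.

The regressor is a SqueezeNet-style 3D CNN: four fire stages (1³ squeeze +
3³ expand convolutions, ReLU), 2³ max-pooling after stages 1 and 2,
dropout 0.5 before stage 4, global average pooling, and a linear head
initialized at the mean training label; MSE loss, Adam optimizer, optional
per-channel z-scoring and rotation augmentation over the 24 proper cube
rotations (index permutations, hence lossless and label-invariant). The
implementation is hand-written RcppArmadillo with analytic gradients — no
deep-learning framework is available offline — and a degenerate-network
oracle test pins the forward semantics. Training is fully deterministic
under the config seed.

## 4. The synthetic generator: realism and limits

Structures are ideal α-helices (CA at radius 2.3 Å, 100°/1.5 Å per
residue) dressed with rigid residue templates of correct connectivity and
composition (C/N/O/S only). `generateBundle()` packs up to 7 parallel
helices on a hexagonal lattice with a deterministic clash-free placement
search; `packEnvironment()` fills a target region with free-standing
clash-checked residues up to a stated atom density. These choices
reproduce what matters for density statistics — atom density, element
composition, bonded-distance geometry — while making no claim to
realistic rotamers, backbone variety, hydrogen bonding or crystal packing.

Model errors are parametric perturbations (per-atom jitter with calibrated
RMSD, sidechain rotation about CA–CB, segment shifts, rigid-body motion)
rather than homology-model or refinement artifacts: perturbation magnitude
gives direct control of the label distribution, at the cost of error
*textures* that are simpler than real mistraced loops.

Problem sizes in the shipped tests are the package's own desk-scale
choices: corpora of 12 training + 3 held-out structures with 12 residues
each, 3 residue types, 6 Å / 0.75 Å boxes (8³ voxels) and a reduced
network trained for 25 epochs. At that scale the pipeline recovers
held-out bCC with pooled Pearson r ≈ 0.75 and improves monotonically with
corpus size over {200, 800, ~2000} records. Production-scale boxes are
24³ (12 Å at 0.5 Å) and the default `cnnConfig()` mirrors the reference
protocol (lr 1e-5, 40 epochs, all 24 rotations); nothing in the
implementation is specific to the reduced sizes.

## 5. Worked micro-example

```{r}
s <- generateStructure(8, seed = 3)
obs <- simulateObservedMap(s, dMin = 1.8, noiseSigma = 0.05, seed = 4)
bad <- perturbStructure(s, perturbationSpec("jitter", 1.5, seed = 1))
rbind(correct = summary(perResidueBcc(s, obs, spacing = 1)$bcc),
      jittered = summary(perResidueBcc(bad, obs, spacing = 1)$bcc))
```

## 6. Design decisions and limitations (summary)

* P1 only; generated cells are orthogonal bounding boxes padded by 6 Å so
  12 Å boxes of edge residues stay meaningful under periodicity. No
  symmetry expansion is implemented.
* Coordinate I/O uses bio3d for atom records with hand-written unit-cell
  handling (CRYST1/`_cell`) and a full-column PDBx `atom_site` writer;
  CCP4/MRC mode-2 map I/O is implemented natively, normalizing arbitrary
  axis orders on read.
* Resolution series are pure Fourier truncations; real pipelines re-refine
  per resolution, which couples the model to the truncated data in ways
  truncation does not reproduce.
* RSCC is a mask approximation (all grid points within 1.5 Å of any
  residue atom, unweighted), documented as such; it is a baseline for the
  bias contrast, not a reference implementation of any particular program.
* The CLI writes a resolved JSON run-config next to every output; any run
  is replayable bit-identically (modulo float32 map serialization) from
  that file alone.
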