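---
title: "Methods: quantifying parallel character displacement from landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying parallel character displacement from landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodisp)
```

## The question and the model

Two competing species meet in sympatric localities on several separate
geographic transects; everywhere else each occurs alone.  If competition
drives character displacement, shape should diverge in sympatry — and if
the competitive mechanism is the same on every transect, the
allopatry-to-sympatry change should be *parallel*: the same amount and the
same direction of shape change on each transect, within each species.

`morphodisp` formalizes this with three layers:

1. **Shape.** Specimens are `k` 2-D landmarks.  Generalized Procrustes
   analysis (GPA) removes position, scale and rotation; Procrustes
   residuals at the consensus are expressed in an orthonormal tangent-space
   basis of partial warps plus two uniform components (`p = 2k - 4`
   variables).  Because the basis is orthonormal, Euclidean geometry in the
   shape variables equals tangent-space Procrustes geometry; every
   statistic downstream is therefore basis-independent, which the test
   suite exploits by asserting invariance under random orthonormal
   rotations of the variables.
2. **Mean structure.** A factorial multivariate linear model
   `shape ~ species * locality * transect` (sum-to-zero coding), reported
   with Pillai's trace and its standard *F* approximation.  Least-squares
   cell means are the model's predictions at each design cell; with effect
   coding any extra factor (sex) is held at its balanced value.
3. **Vectors and inference.** Per species and transect, the evolution
   vector is the sympatric minus allopatric LS mean.  Its magnitude `d`,
   within-species pairwise magnitude differences `MD` and angles `theta`,
   the pooled heterogeneity summaries `Var_size` and `Var_orient`, and the
   between-species angle are all assessed by residual randomization
   (RRPP): permute whole residual rows of a reduced model, add them back
   to its fitted values, refit the full model, recompute every statistic;
   `p = (1 + #{null >= obs}) / (nperm + 1)`.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `nperm` | 999 (9,999 in the default design) | permutations | design standard for permutation inference |
| GPA tolerance | 1e-10 | change in residual SS | well below any biological signal; converges in < 10 iterations |
| GPA iteration cap | 100 | iterations | generous; non-convergence raises an error carrying the last change |
| `alpha` | 0.05 | — | experiment-wise rate, Bonferroni within each family of transect pairs (m = 3 per species per statistic type) |
| deformation grid | 24 x 24 cells, 10 % margin | — | legible grids at typical figure sizes |
| displacement magnitude | 0.05 | Procrustes (tangent radian) units | realistic small-shape-change scale; a warning is raised above 0.2 where tangent linearity degrades |
| `noise_sd` | magnitude / sqrt(2k - 4) | coordinate units | makes per-specimen shape standard deviation comparable to the vector magnitude — a hard but realistic signal-to-noise regime |
| species offset | 0.1 | Procrustes units | the species effect dominates the locality effect, as in real contact zones |
| sex effect | 0.04 (default design) | Procrustes units | sexual dimorphism of the same order as displacement |

## What the generator emulates — and what it does not

`simulate_shapes()` builds a 2 species x 2 locality types x 3 transects
design around a deterministic head-like template: per-cell mean shapes are
tangent-space displacements of the template, specimens add isotropic
Gaussian landmark noise, an optional fixed sex displacement splits each
cell, and optional per-specimen similarity transforms (rotation,
translation, scaling) emulate arbitrary specimen placement.  Scenarios fix
the truth: `parallel` (identical within-species vectors, species directions
separated by a configurable angle, default 47.71 degrees), `null` (no
displacement), `divergent(theta)` (within-species directions pairwise
`theta` apart), and `magnitude_heterogeneous` (common direction, scaled
lengths).

Two constructions keep the truth exact rather than approximate.  Cell
means are mapped to configuration space as
`sqrt(1 - |t|^2) * template + B t`, which preserves tangent norms exactly,
and the per-cell displacements are centered so their design mean is zero —
then for balanced noise-free data the Procrustes consensus coincides with
the template and the generating magnitudes and angles are recovered to
machine precision.  Neither step changes any vector difference, magnitude
or angle.

The generator does **not** emulate: correlated landmark noise (digitizing
error is near-isotropic but biological covariance is not), unequal
per-locality sample sizes, allometry, measurement error in sexing, or any
genetic structure.  A green recovery test therefore establishes that the
*estimator chain* is correct, not that real salamander heads satisfy the
model.  Note also that truth is defined in the all-landmark tangent space;
under a separate-subset analysis the per-subset rescaling changes
magnitudes and angles, so exact-recovery tests use the single-subset
analysis.

## Numerical choices

* **Rotations only.**  Fitting rotations are constrained to determinant
  +1; biological landmark data have a fixed orientation and a reflection
  is never an admissible fit.
* **Canonical orientation.**  After convergence the whole GPA solution is
  rotated so the consensus' major principal axis lies along x (sign fixed
  by the landmark of largest |x|), and each partial-warp eigenvector's
  sign is fixed by its largest component.  Without these conventions the
  individual shape variables are only defined up to rotations/sign flips
  and would differ between runs on rotated copies of the same data.
* **Two consensus objects.**  The unit-centroid-size consensus drives the
  tangent projection; the reported `consensus` is the arithmetic mean of
  the aligned specimens (its size is 1 only up to the shape variance).
* **Angles.**  Computed as `2 atan2(|u/|u| - v/|v||, |u/|u| + v/|v||)`,
  which is exact near 0 and 180 degrees where the arccosine of a clamped
  dot-product ratio loses half the significant digits.  Reported in
  degrees.
* **Uniform components.**  The affine subspace of tangent space is 2-D;
  the free rotation within it is fixed by orthonormalizing the projected
  x-shear field first and orienting the remainder along the projected
  y-dilation field.
* **Degenerate permutations.**  A permutation that yields a zero-length
  vector leaves its angle undefined; such statistics count toward the
  null tail (conservative) and are tallied in the result.
* **Ties.** Null values within 1e-12 (relative) of the observed statistic
  count as `>=`, so exact recomputations of the observed arrangement are
  never undercounted.

## Design decisions that were genuinely open

**The skull/jaw partition.**  Twelve landmarks under a separate-subset
analysis yield 18 shape variables only if the two subsets jointly use 13
landmark slots, e.g. 7 + 6 with one shared articulation landmark.  The
partition is user-supplied configuration (`landmark_partition()`), and the
default design's `skull = 1:7, jaw = 7:12` is one such choice, not an
anatomical claim.

**`Var_size` and `Var_orient`.**  Two published readings exist for each.
Defaults: `Var_size` is the pooled variance of the within-species vector
magnitudes about their species means (denominator N - S); `Var_orient` is
the sample variance of the pooled within-species pairwise angles.  The
alternatives (variance of pairwise magnitude differences; pooled
within-species angle variance) are available by argument.  Both are zero
exactly when evolution is perfectly parallel within species.

**Reduced models for RRPP.**  The default null for the within-species
pairwise and variance statistics drops only the three-way
species x locality x transect interaction, i.e. it tests whether the
displacement pattern differs among transects in a species-specific way.
For the between-species angle this reduced model would be self-defeating:
it retains species x locality, so the null data keep species-specific
displacement vectors and the observed angle is typical of its own null.
The between-species test therefore also drops species x locality — its
null is "one common displacement vector for both species".

**Calibration of the vector tests** (measured, not assumed — the
acceptance suite recomputes this).  Under a *zero-displacement* null the
default within-species tests are not exactly calibrated: magnitude tests
are conservative and angle tests somewhat inflated, because noise fitted
into the retained interaction terms of the reduced model is held fixed
across permutations.  Dropping `locality:transect` as well (available via
the `reduced` argument) calibrates the magnitude tests but inflates the
angle tests further.  Under the realistic null for this design — a real,
transect-homogeneous displacement — the default tests are conservative
for both statistic types.  Angle statistics are intrinsically fragile
when vectors are noise-length (the angle of a zero vector is undefined);
conclusions about orientation should only be drawn when the magnitudes
themselves are clearly nonzero.

## Known limitations

* 2-D landmarks only; no semilandmarks, no missing-landmark estimation.
* Tangent-space linearity is assumed (small shape variation); the
  generator warns beyond 0.2 Procrustes units.
* The canonical orientation is undefined for consensus shapes with an
  isotropic landmark covariance (exactly circular configurations).
* LS means require every analysed design cell to be estimable; empty
  cells fail at design construction with the offending term named.
* Two-point trajectories only (allopatry to sympatry); multi-point
  trajectory shape analysis is out of scope.
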