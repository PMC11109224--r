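---
title: "Left atrial volumetry and downstream genetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial volumetry and downstream genetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriumkit)
```

## The problem

Cine cardiac MRI images the heart as a few fixed 2D planes: single
two-, three- and four-chamber long-axis views (≈1.83 mm pixels, 6 mm
thickness) plus a short-axis stack of 8 mm planes with ≈2 mm gaps, each
acquired as 50 frames over one cardiac cycle. None of these views captures
the left atrium (LA) in 3D, so per-view segmentation masks must be fused
into one volumetric estimate per frame. From the resulting volume trace the
package derives the standard LA phenotypes — LAmax, LAmin, LASV = LAmax −
LAmin and LAEF = LASV/LAmax, optionally indexed to body surface area — and
provides the genetics statistics applied to such phenotypes: distance-based
locus definition, locus-overlap enrichment, Hardy-Weinberg checks, and
two-sample Mendelian randomization (MR).

## Surface reconstruction

### From masks to an oriented point cloud

Pixel (r, c) of a view maps to patient coordinates through the DICOM
convention P = S + c·Δc·X + r·Δr·Y (0-based indices, pixel centres), with S
the Image Position, X/Y the Image Orientation direction cosines and Δr/Δc
the pixel spacing. The mask perimeter (mask minus its erosion by a 3×3
cross; the structuring element is configurable) supplies the points. Each
point's normal is the direction from the 3D centroid of *all* segmented
pixels of that mask to the point, projected onto the view plane and
renormalised — so normals are unit, in-plane and radially outward. The
full-mask centroid (rather than the perimeter centroid) is used because the
mask interior is the better-conditioned estimate of the chamber centre for
crescent-shaped cross-sections; for convex sections the two coincide. A
perimeter point coinciding with the centroid has no direction and is
dropped with a warning rather than given a zero normal, so the solver never
receives non-unit normals.

Fragments from all views are pooled per frame. A frame is reconstructable
only if the pooled points are not all coplanar; this is tested on the
singular values of the centred point matrix (third singular value >
1e-7 × the first). A cine study is reconstructable when at least two
distinct plane orientations are present.

### The indicator solve

The indicator function χ (≈1 inside the chamber, ≈0 outside) satisfies
∇χ = V⃗ with V⃗ the inward-oriented surface normal field concentrated on the
surface. The package recovers χ by:

1. bounding the points, padding by 25% per side, and laying a cubic grid of
   `grid_res = 96` nodes per axis (the cube side is the largest padded
   extent, so voxels are isotropic);
2. splatting each point's (sign-flipped, inward) normal trilinearly into a
   vector field and smoothing with an isotropic Gaussian of
   `smoothing_sigma_vox = 1.5` voxels;
3. solving ∇²χ = ∇·V⃗ with zero-Dirichlet boundary. Because the grid is
   regular and the Laplacian is the standard 7-point stencil, the solve is
   done exactly by diagonalisation with the type-I discrete sine transform
   (implemented as dense matrix products along each axis) — there is no
   iteration, no tolerance, and the cost is a few BLAS products per frame;
4. setting the iso-value to the mean of χ sampled trilinearly at the input
   points, the standard convention for indicator-based reconstruction.

Because the points sample the surface only along plane-intersection curves
(dense along each perimeter, absent between planes), each point's splat
weight is divided by the local point density (the smoothed splat of ones
sampled at the point), so heavily sampled curves do not dominate the field.
This density normalisation is on by default and can be disabled.

The reference implementations of this family of methods use adaptive
octrees and screening; this package deliberately uses a flat grid without
screening — the same mathematical object, with accuracy governed by the
volume-recovery property below rather than bit-compatibility with any
particular library.

### Mesh extraction and volume

The iso-surface is extracted by marching tetrahedra: each grid cube is
split into the six Kuhn tetrahedra, a decomposition that is face-consistent
across cubes, so the extracted triangle mesh is watertight by construction
and has no ambiguous configurations (the reason it is preferred here over
classic marching cubes). Triangles are oriented from the high-χ side to the
low side, the global orientation is fixed so the signed volume is positive,
and only the largest connected component is retained (multi-component
segmentations are flagged separately by QC). Volume is the divergence
theorem sum of signed tetrahedra over the closed mesh, converted mm³ → mL.
`mesh_volume()` refuses non-watertight input and lists the open edges.

Frames whose reconstruction fails (coplanar points, degenerate fields)
carry an NA volume plus the error message in the trace status — never a
zero — so that phenotype extraction can refuse incomplete traces
explicitly.

### Accuracy

The test suite checks, against closed-form volumes: spheres and ellipsoids
with 20–60 mm semi-axes sliced by the default view plan are recovered
within 5% at `grid_res` 96 (observed errors are within about ±4%); the mean
absolute error at resolution 96 is below that at 32 over five radii;
rigidly transforming all plane geometries changes the volume by < 1%; and a
pulsating-sphere phantom's extremal frames are located within ±1 frame.
Test problem sizes are kept small deliberately — single frames for the
recovery checks, 25 frames at resolution 48 for the pulsation check —
because the properties are resolution-governed, not sample-size-governed.

## Quality control and mask metrics

Four per-study heuristics, applied to the segmentation before
reconstruction: (a) any frame with more than one connected component
(8-connected by default; configurable); (b) a maximum frame-to-frame change
in segmented pixel count exceeding the cohort mean by more than five cohort
standard deviations (the cohort statistics are computed over the batch
passed in, matching the "population" semantics, and can be persisted); (c)
any empty frame; (d) a frame count different from 50. "More than one
component" is evaluated per frame and the study is flagged if any frame
violates it. Flags are reported, and flagged studies have phenotypes
withheld rather than silently dropped.

Mask-quality metrics follow the conventions of segmentation evaluation:
Dice 2|A∩B|/(|A|+|B|) (defined as 1 for two empty masks); the *directed*
Hausdorff distance (max over perimeter points of a of the nearest-point
distance to the perimeter of b) — directed because model-output-to-truth is
the quantity of interest, with a symmetric option; and the mean contour
distance (mean instead of max). Distances are between pixel centres in mm.
All three are verified exactly against an O(N²) brute-force oracle on
random masks up to 16×16.

## Phenotypes and filling curves

`la_phenotypes()` requires a complete trace and returns LAmax, LAmin, LASV
and LAEF, with BSA-indexed counterparts when a body surface area is given.
BSA uses Du Bois (0.007184·kg^0.425·cm^0.725) by default — the prevailing
cardiology convention — with Mosteller as an option.

The 50×8 filling-curve tensor holds per-chamber pixel counts from the three
long-axis views (4ch: LA, RA, LV, RV; 3ch: LA, LV; 2ch: LA, LV), each
channel normalised by its own maximum over the 50 frames so only relative
size changes remain. The per-channel maximum is taken over the frames of
that channel only (not across views). Cases missing any channel, or with a
zero-maximum channel, are excluded with an error. The abnormal-filling
classifier proper is a pluggable interface; the shipped rule — "normal"
when the mean LA channel shows a late-cycle dip deeper than 5% of the
normalised range — is package plumbing for exercising the interface, not a
trained model, and is documented as such.

## Locus definition, overlap, and HWE

Distinct loci are defined greedily: order lead SNPs by ascending P (ties
broken by chromosome and position, so the result is deterministic and
order-invariant), take the strongest, absorb everything within the window
on the same chromosome, iterate. "Within 500 kb" is inclusive
(|Δbp| ≤ 500,000); the window is configurable. Cross-trait distinct loci
are obtained by pooling all trait tables and merging the pooled set — this
procedure reproduces every per-trait, shared and pooled count printed for
the packaged lead-SNP table (5/8/4/2 per trait, 4 shared, 3
indexed-only, 20 pooled). Locus sharing between two sets matches leads
within the window greedily by increasing distance, each lead used once.

The overlap enrichment test counts LA loci with at least one reference lead
within the window (a locus counts once, however many reference SNPs fall
near it) and compares against null SNP sets of the same size. Null-set
construction is pluggable — the matched-set generators used in GWAS
practice condition on allele frequency, LD and gene density, which requires
external panels — and a uniform sampler over a user-supplied panel ships as
the default. The one-tailed p-value uses the add-one rule, whose floor with
10,000 sets is 1/10,001 ≈ 1E-04. The test suite checks the p-value's
distribution under exchangeability against an independent hypergeometric
rank oracle.

Hardy-Weinberg equilibrium uses the exact conditional test: given the
allele counts, all heterozygote counts of matching parity are enumerated
with a stable probability recurrence, and the two-sided p sums the
probabilities no larger than the observed one. It agrees with a direct
log-factorial enumeration oracle for totals up to 200 (tested) and flags
extreme heterozygote excess well beyond the 1E-06 threshold used for lead
SNPs.

## Mendelian randomization

Instrument selection filters to p < 1e-6 and thins by the same greedy
distance merge with a 5 Mb radius. True LD-based clumping needs a genotype
reference panel, which the package does not ship; distance-only thinning is
the documented stand-in, with threshold and radius configurable.
Harmonization matches variants by rsid (falling back on chr:bp), removes
palindromic A/T and C/G variants (strand cannot be resolved from alleles
alone), flips the outcome beta when the outcome's alleles are swapped
relative to the exposure, and drops irreconcilable allele pairs with a
warning.

Estimators, for harmonized effects (βx, βy, σy):

* **IVW**: θ̂ = Σ(βxβy/σy²)/Σ(βx²/σy²), identical to the weighted
  through-origin regression (verified against an independent `lm` oracle).
  The default standard error is multiplicative random effects — the
  fixed-effect SE scaled by max(1, √(Q/(k−1))) — because heterogeneity is
  the rule for cardiac phenotypes; fixed effects by flag.
* **MR-Egger**: weighted least squares with intercept after orienting every
  instrument to βx ≥ 0 (required for identifiability; the intercept
  estimates directional pleiotropy on the exposure-increasing-allele
  scale). Residual overdispersion is floored at 1, consistent with the IVW
  convention. Optional nonparametric bootstrap over instruments.
* **Medians**: per-variant Wald ratios βy/βx; simple median, and the
  interpolated weighted median with first-order inverse-variance weights.
  SEs come from resampling instruments, so identical ratios give exactly
  zero spread. Zero exposure effects are dropped with a warning.
* **Cochran Q** on Wald ratios with first-order weights, χ²(k−1).

The pleiotropy screen regresses each measured risk factor on each
instrument's dosage (plus covariates; any numeric coding is accepted,
since medication/smoking codings vary by cohort) and flags instruments
crossing the Bonferroni threshold α/(k·m) — 0.05/(19·7) ≈ 3.8E-04 for the
canonical 19-instrument, 7-factor screen — marking them for a leave-out
sensitivity rerun. Robust-outlier methods (MR-PRESSO, contamination
mixture) are out of scope; the report schema's method column is free text
so externally computed rows can be merged.

Test properties: exact agreement of IVW with the regression oracle up to
10 instruments; sign equivariance; recovery of a planted θ within
Monte-Carlo error; 95% CI coverage of all four estimators within binomial
error over 500 simulated 50-instrument sets; Egger intercept centred on a
planted directional pleiotropy of 0.05 and on 0 under balanced pleiotropy.

## Synthetic data: what it emulates, what it does not

`make_phantom()` slices time-varying spheres/ellipsoids (or two disjoint
lobes) with the default acquisition plan — three long-axis planes at
0°/60°/120° about the long axis plus a 6-slice short-axis stack (8 mm
planes, 2 mm gaps), 1.83/1.86 mm pixels — and returns binary cine masks
with full geometry sidecars plus the closed-form volume per frame.
Rasterisation uses the boundary-coverage convention: a pixel is foreground
when its centre lies within half a pixel of the surface, so perimeter pixel
centres straddle the analytic contour rather than sitting systematically
half a pixel inside it (the bias a centre-inside convention would imprint
on any perimeter-based reconstruction, and analogous to annotators
including partially covered boundary pixels). Optional boundary jitter
perturbs the rasterisation threshold by a seeded Gaussian of the requested
pixel scale, emulating segmentation noise without touching the geometry
sidecar. All generators are pure functions of spec + seed.

The phantoms are convex and smooth: no appendage, pulmonary veins, wall
irregularity, or through-plane motion, and masks are perfectly consistent
across views up to rasterisation. Passing the recovery properties therefore
demonstrates correctness of the geometry/solver chain, not performance on
real atria — on real data, segmentation error and anatomical complexity
dominate.

`make_filling_curves()` produces smooth two-phase atrial curves with or
without the late-cycle atrial-contraction dip (the feature that is absent
in atrial fibrillation) and anti-phase ventricular channels; it labels each
case for classifier-interface tests. `make_leadsnp_table()` plants a known
cluster structure (within-cluster span below, between-cluster gaps above
the merge window) so locus counts are known by construction.
`make_mr_dataset()` draws exposure effects, forms outcome effects as
θβx + pleiotropy + noise with SEs set by the two sample sizes, applies
direct effects relative to the exposure-increasing allele (so directional
pleiotropy survives allele re-orientation), and plants configurable
fractions of palindromic and allele-swapped variants to exercise
harmonization. Exposure effects are reported without estimation noise, so
estimator checks isolate estimator behaviour from winner's-curse and
weak-instrument bias, which are real-data phenomena the simulations do not
model.

## Numerical choices and degenerate inputs

* Coplanarity threshold: s₃ ≤ 1e-7·s₁ on centred singular values.
* Perimeter structuring element: 3×3 cross (4-connectivity), configurable
  to the 3×3 square.
* Component connectivity: 8-connected by default, configurable to 4.
* Iso-extraction requires the iso-value strictly inside the field range; a
  constant field is an error, an inverted field (all normals flipped)
  yields the complementary region and is caught by the orientation fix.
* Greedy merges break P ties by (chromosome, position); shared-locus
  matching breaks ties by distance, first-come on exact ties.
* Bootstrap seeding: a single integer seed; RNG state is restored around
  every seeded block, so library calls never perturb user RNG streams.
* The permutation add-one rule keeps p in (0, 1]; an observed overlap of 0
  gives p = 1.

## The run layer

`run_imaging_study()` chains cohort QC → reconstruction → phenotypes over a
batch of studies, withholds phenotypes for flagged studies, records
failures per study without aborting the batch, and writes TSV/CSV/JSON
outputs with fixed formatting so reruns are byte-identical given the same
config and seed. `run_genetics_study()` chains per-trait and pooled locus
definition with optional overlap permutation and MR reporting. Both record
parameters and seeds in a manifest JSON. These functions, the exported
operations and this vignette are the package's interface; no shell wrapper
is shipped because the intended users drive analyses from R.

## Known limitations

* Unscreened, flat-grid Poisson: very anisotropic chambers waste grid
  resolution along short axes; accuracy degrades if the object occupies a
  small fraction of its padded bounding cube.
* Distance-based clumping is not LD clumping; in regions of long-range LD
  the instrument count can differ from an LD-aware pipeline.
* The uniform null-set provider does not match on allele frequency, LD or
  gene density; enrichment p-values against biased reference lists should
  be read accordingly, and a matched provider can be plugged in.
* The filling-pattern rule is a stand-in for a trained classifier and
  should not be used for clinical exclusion decisions.
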