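# atriumkit

Left atrial (LA) volumetry from multi-view cardiac MRI segmentations, and the
genetics statistics that sit downstream of it.

Cardiac MRI protocols image the heart as a handful of 2D planes — three
long-axis views plus a short-axis stack — so no single view captures the left
atrium in 3D. Given binary LA segmentation masks for each view (50 frames per
cardiac cycle) and the DICOM plane geometry, `atriumkit` fuses the views into
a watertight 3D surface per frame and reads off the chamber volume, yielding
the standard LA phenotypes: maximum volume (LAmax), minimum volume (LAmin),
stroke volume (LASV = LAmax − LAmin) and emptying fraction (LAEF =
LASV/LAmax). It is written for imaging-genetics analysts who need the full
chain — segmentation QC, reconstruction, phenotype extraction, GWAS locus
arithmetic, enrichment testing and Mendelian randomization — as tested,
scriptable R functions, with synthetic generators supplying ground-truth data
for every stage.

## The methods at the core

**Poisson surface reconstruction.** Each mask's perimeter pixels are mapped
into patient coordinates through the DICOM Image Position/Orientation
mapping, giving a sparse 3D point cloud; each point carries an in-plane
normal pointing radially away from the mask's centre of gravity. The chamber
indicator function χ (≈1 inside, ≈0 outside) satisfies ∇χ = V⃗, where V⃗ is
the (inward-oriented) surface normal field, so χ is recovered by solving the
Poisson equation

    ∇²χ = ∇·V⃗

on a regular grid (zero-Dirichlet boundary, exact sine-transform solver)
after splatting and smoothing the normals. The surface is the iso-level of χ
at the mean of χ over the input points, extracted by marching tetrahedra, and
the volume follows from the divergence theorem over the closed mesh.

**Locus arithmetic.** GWAS lead SNPs are merged into distinct genomic loci
greedily: take the SNP with the smallest P, absorb all SNPs within 500 kb on
the same chromosome, repeat. Overlap of LA loci with a reference lead-SNP
list (e.g. atrial fibrillation loci) is tested by permutation against
matched null SNP sets, with the one-tailed p-value
`(1 + #{null ≥ observed}) / (1 + n_sets)`. Lead SNPs are checked for
Hardy-Weinberg equilibrium with the exact conditional test.

**Two-sample Mendelian randomization.** After distance-based instrument
selection (p < 1e-6, 5 Mb radius) and allele harmonization (palindromic
variants removed, swapped outcome alleles flipped), causal effects are
estimated by inverse-variance weighting

    θ̂_IVW = Σ(βx βy / σy²) / Σ(βx² / σy²)

with multiplicative random-effects standard errors, plus MR-Egger (intercept
= directional pleiotropy), simple and weighted medians (bootstrap SEs),
Cochran's Q heterogeneity, and a Bonferroni-corrected pleiotropy screen of
instruments against measured risk factors.

## Worked example

Reconstruct a pulsating spherical phantom (radius 27 ± 4 mm over the cycle)
from its own sliced masks — 3 long-axis planes and a 6-slice short-axis
stack — then extract phenotypes:

```r
library(atriumkit)
spec <- phantom_spec("sphere",
                     semi_axes_mm = function(t) rep(27 + 4 * sin(2 * pi * (t - 1) / 10), 3),
                     n_frames = 10)
ph <- make_phantom(spec)
tr <- reconstruct_trace(ph$views, grid_res = 96)
print(tr)
#> <volume_trace> 10 frames, 0 failed
#>   volume range 53.7 - 124.5 mL
la_phenotypes(tr, bsa_m2 = 1.9)
#> LA phenotypes: LAmax 124.5 mL, LAmin 53.7 mL, LASV 70.8 mL, LAEF 56.8%
#>   BSA-indexed (BSA 1.90 m2): LAmax 65.5, LAmin 28.3, LASV 37.2 mL/m2
```

The analytic truth for this phantom is LAmax 122.4 mL / LAmin 52.3 mL, so
the reconstruction is within about 2% at every frame. On the genetics side,
the packaged LA lead-SNP table reproduces the locus structure of the LA
GWAS:

```r
tab <- la_lead_snps()
merge_loci(tab[tab$trait == "LAEF", ])
#> <locus_set> 4 loci (window 500 kb)
#>   chr14: 23,874,117  lead p=7.3e-14  members=1
#>   chr1:116,310,967  lead p=7.8e-11  members=1
#>   chr22: 26,159,289  lead p=3.6e-10  members=1
#>   chr1: 51,322,205  lead p=4.7e-08  members=1
length(distinct_loci_across_traits(split(tab, tab$trait)))
#> [1] 20
```

and a simulated two-sample MR dataset with true effect θ = 0.5 is recovered
by the estimators:

```r
d <- make_mr_dataset(k = 50, theta = 0.5, frac_palindromic = 0.1, seed = 7)
set <- harmonize(select_instruments(d$exposure), d$outcome)
mr_ivw(set)
#> IVW (multiplicative random effects): estimate 0.4976 (SE 0.0159, 95% CI 0.4664 to 0.5288), p = 2.7e-214, k = 45
#>   Cochran Q = 34.647 (df 44), p = 0.843
```

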