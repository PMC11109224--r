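Package: atriumkit
Title: Left Atrial Volume Reconstruction from Multi-View Cine Segmentations and Downstream Genetic Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs left atrial (LA) volume traces from sparse multi-plane
    cine MRI segmentation masks by Poisson indicator-function surface
    reconstruction, derives LA phenotypes (maximum and minimum volume, stroke
    volume, emptying fraction) with quality-control heuristics and
    segmentation-quality metrics (Dice, directed Hausdorff, mean contour
    distance), and implements the downstream genetics statistics: greedy
    500-kb locus definition from GWAS lead-SNP tables, permutation enrichment
    of locus overlap against a reference lead-SNP list, Hardy-Weinberg exact
    tests, and two-sample Mendelian randomization (inverse-variance weighted,
    MR-Egger, simple and weighted median) with harmonization and a pleiotropy
    screen. Synthetic generators provide sliced geometric phantoms with known
    analytic volume, chamber filling curves, lead-SNP tables, and MR
    instrument sets with known causal effects, so every component is testable
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    RNifti,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
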