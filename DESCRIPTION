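Package: rilmap
Title: Linkage Maps, Recombination Rates and QTL from Low-Coverage
    RIL Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building dense genetic linkage maps from
    low-coverage genotyping-by-sequencing of selfed recombinant inbred
    lines (RILs). Implements a SNP filter cascade and window-based
    genotype caller for sparse allele-depth data, single-linkage
    grouping and scaffold-constrained marker ordering with Haldane map
    distances corrected for repeated selfing, per-scaffold and global
    recombination-rate estimation (cM/Mb) with geometric block-bootstrap
    confidence intervals, detection of recombination-suppressed blocks
    (putative inversions), and QTL mapping of quantitative phenotypes by
    multiple-imputation interval mapping with permutation-based LOD
    thresholds. A pedigree-accurate simulator of selfed-RIL panels with
    full ground truth supports end-to-end verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    lme4
Config/testthat/edition: 3
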