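Package: hatchscan
Title: Trait-Associated Loci and Divergence Scans for Captive-Reared Salmon Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for monitoring domestication selection in supportive
    breeding programs with paired integrated (managed gene flow) and segregated
    (closed) hatchery lines. Provides depth-based RAD-seq genotype calling and
    quality control (minor allele frequency, missingness, exact Hardy-Weinberg
    filtering, frequency-based imputation), cross-genome anchoring of unmapped
    loci onto a linkage map, random-forest association for polygenic fitness
    traits with confounder correction, ntree stability tuning and backward
    purging, per-locus Weir-Cockerham FST with a temporal drift-simulation
    outlier test and kernel-smoothed sliding-window scans against resampled
    nulls, phenotype contrasts between lines, PCA trajectories of
    trait-associated loci, and trait-by-outlier overlap reports. A
    Wright-Fisher simulator of the two-line study design generates genotypes,
    read depths, linkage maps, proxy-genome alignments and phenotypes with
    known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
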