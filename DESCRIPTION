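Package: dupsnp
Title: SNP Array Genotyping and Linkage Grouping for Duplicated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for developing and analysing high-density SNP genotyping
    arrays in species with duplicated genomes such as Atlantic salmon.
    Implements candidate-SNP filtering against paralogous sequence variants
    (haploid-heterozygote exclusion, allele-frequency/depth thresholds,
    repeat masking, Mendelian-error and segregation-distortion filters),
    Axiom-style intensity-based genotype calling (quantile normalisation,
    median-polish probe summarisation, contrast-size transform, boundary-scan
    initialisation of a Bayesian Gaussian mixture, off-target-variant
    detection by EM), six-category SNP quality classification, chromosome
    assignment by two-point LOD linkage exploiting absent male recombination,
    identity-by-state distance and classical multidimensional scaling for
    population structure, and Y-probe genetic sexing. A synthetic-data module
    generates genomes with paralogs, structured populations, pedigrees,
    candidate variants, probe intensities and Y-probe signals with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
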