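Package: kinflow
Title: Gene Flow Inference for Small Spatially Mapped Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Direct and indirect gene flow estimation from biallelic SNP
    genotypes in small, spatially mapped plant populations. Implements
    pairwise kinship and relatedness estimators (Loiselle, Ritland,
    Queller-Goodnight) with jackknife-across-loci uncertainty; distance-class
    analysis of fine-scale spatial genetic structure with the Sp statistic,
    Wright's neighborhood size and indirect dispersal distance; likelihood
    based categorical parentage assignment with simulated Delta criteria,
    non-exclusion probabilities, cryptic gene flow and pollen/seed dispersal
    summaries; missing-data by minor-allele-frequency filter sensitivity
    grids; and spatially explicit pedigree and isolation-by-distance
    simulators so every stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, graphics, utils, vcfR
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
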