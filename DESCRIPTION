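Package: fragpop
Title: Population-Genomic Analysis of Barrier-Fragmented River Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-species riverine population genomics from RADseq
    SNP genotypes: post-genotyping quality filters (call rate, minor allele
    count, HDPlot paralog detection, one SNP per RAD tag), Weir-Cockerham
    FST and diversity summaries with a permutation differentiation test,
    PCA and admixture-model ancestry inference with cross-validated K
    selection and Q-score group reassignment, linkage-disequilibrium
    effective population size with chromosome-number bias correction,
    Wang-type moment relatedness, ecological group comparisons, and a
    forward-in-time two-deme Wright-Fisher simulator of divergence across a
    barrier with asymmetric downstream migration. A synthetic-data module
    generates genotype matrices, read depths, metadata and pedigree spikes
    with the statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
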