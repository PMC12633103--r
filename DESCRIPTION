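Package: svomics
Title: Structural-Variant Multi-Omics QTL Mapping, Fine-Mapping and Colocalization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-scale structural-variant (SV)
    analysis with matched multi-omics data: allele-frequency and
    discovery-saturation analysis of SV call sets, expression/protein/methylation
    normalization and molecular-outlier calling, rare-SV outlier enrichment and
    prioritization, interval-aware cis SV-QTL mapping with covariates and
    phenotype principal components, Sum-of-Single-Effects fine-mapping over
    combined SV and SNV genotypes with credible sets, and approximate-Bayes-factor
    colocalization against GWAS summary statistics. Ships a synthetic-data
    generator with known ground truth so every stage can be validated without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
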