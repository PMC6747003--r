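Package: cistrio
Title: Cis-Regulatory Pattern Analysis of SNP-mRNA-Protein Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps cis expression, protein, and protein-specific quantitative
    trait loci (eQTLs, pQTLs, psQTLs) from genotype dosage, mRNA, and protein
    abundance matrices; classifies each QTL-gene trio into one of six
    SNP/mRNA/protein regulatory patterns by Gaussian maximum likelihood and
    BIC model selection; and quantifies chromatin-state and genomic-location
    enrichment of QTLs per pattern. Includes a synthetic cohort generator
    with known generative pattern per gene so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
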