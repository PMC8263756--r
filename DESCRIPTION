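Package: loyburden
Title: Rare-Variant Gene Burden Analysis of Mosaic Loss of Chromosome Y
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying germline genetic determinants of mosaic
    loss of chromosome Y (LOY) with exome-sequence data. Implements the
    composite quantitative LOY phenotype PAR-LOYq (combining the dichotomous
    PAR-based LOY call, the estimated LOY cell fraction and the median log R
    ratio of Y-specific array probes), variant-site and genotype-level quality
    control of multi-sample VCFs (missingness, read-depth, genotype-quality
    and allelic-balance filters), collapsing of rare coding variants into
    per-gene carrier indicators and dosage matrices, burden, SKAT-style
    variance-component, ACAT-V and Cauchy-omnibus association tests with
    covariate adjustment, and the accompanying sensitivity analyses
    (leave-one-out, variant-subset re-analysis, principal-component
    confounding checks and a multi-trait phenome scan). A synthetic-data
    generator emulates biobank-style cohorts, array LOY measurements, exome
    VCFs with realistic QC fields and phenotypes, so the whole pipeline runs
    end-to-end without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
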