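Package: liabilityGWAS
Title: Age-at-Onset Informed Genome-Wide Association Analysis via the
    Liability Threshold Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a covariate-informed genome-wide association
    workflow for case/control traits with age structure. A liability
    threshold model is calibrated from sex-specific cumulative risk-by-age
    schedules on the probit scale; case/control status and age-at-onset
    (or age-at-observation) are converted to posterior mean liabilities
    via truncated-normal integrals, which are tested against imputed
    genotype dosages with an N times r-squared score test. Downstream
    tooling covers SNP filtering on imputation quality and allele
    frequency, EIGENSTRAT-style covariate residualization, genomic
    control with lambda-1000 scaling, Stouffer and inverse-variance
    meta-analysis with Cochran heterogeneity, distance/LD clumping and a
    three-stage discovery-replication workflow, Bayesian colocalization
    through Wakefield approximate Bayes factors, cis-QTL linear
    regression with Benjamini-Hochberg control, and a fully seeded
    synthetic-cohort generator (age-structured liability sampling, LD
    blocks, imputation-quality degradation, molecular traits) so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation
biocViews: GenomeWideAssociationStudies, SNP, StatisticalMethod,
    GeneticVariability
Config/testthat/edition: 3
RoxygenNote: 7.3.3
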