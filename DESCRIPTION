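Package: rvburden
Title: Case-Control Rare-Variant Collapsing Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based collapsing analysis for case-control sequencing
    studies. Applies hard site and genotype quality filters to cohort
    variant calls, removes related individuals with a robust pairwise
    kinship estimator and population outliers with iterative principal
    component analysis, harmonizes exome coverage between cases and
    controls, collapses ultra-rare functional ("qualifying") variants to a
    gene-by-sample dominant-model indicator matrix, and tests each gene by
    two-tailed Fisher's exact test and Firth penalized logistic regression
    with a per-sample ultra-rare synonymous count as covariate.
    Permutation-based quantile-quantile diagnostics use a
    covariate-preserving weighted-urn label permutation (multivariate
    Fisher noncentral hypergeometric sampling), and known-gene recovery is
    scored by hypergeometric rank enrichment. Includes a synthetic cohort
    generator emulating the statistical structure of a large case-control
    exome study (batch-confounded background variant load, capture-kit
    coverage imbalance, cryptic relatedness, population substructure) so
    the full pipeline is testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
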