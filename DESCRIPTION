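Package: earlyvigor
Title: Functional Growth Analysis and Nutrient Stoichiometry for Early-Vigor
    Phenotyping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing early-vigor rhizobox experiments on juvenile
    cereals: functional growth analysis (relative growth rate and its
    decompositions into leaf-area ratio times leaf-area productivity and plant
    nitrogen concentration times nitrogen productivity), shoot and root
    morphometrics (leaf-area estimation from length and width, partition of
    scanned root length into main and lateral roots by a diameter threshold),
    multi-element nutrient stoichiometry (whole-plant element pools, expected
    pools under optimum nitrogen-based element ratios, pairwise element
    scaling, surrogate productivities, stoichiometric niche volumes and their
    reduced-major-axis scaling exponents), and the statistical surfaces of a
    randomized complete block trial (Pearson correlation matrices, one-way
    ANOVA, genotype slope-heterogeneity with Tukey-adjusted comparisons).
    Includes a synthetic rhizobox-experiment generator with embedded ground
    truth so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
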