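Package: halfsibQG
Title: Variance Components, Heritability and Reaction Norms for Nested
    Half-Sib Breeding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and restricted-maximum-likelihood analysis of nested
    paternal half-sib / maternal full-sib breeding designs with two rearing
    environments, as used in quantitative-genetic studies of behavioural and
    life-history traits.  Provides a breeding-design and phenotype simulator
    with known ground truth, trait construction (censored boldness scores,
    log/sqrt transforms, covariate standardisation), linear mixed model fits
    partitioning phenotypic variance into sire, dam, block, test-day,
    individual and residual components, likelihood-ratio tests of random
    effects (including 2-df reaction-norm genotype-by-environment tests at
    the variance boundary), case-bootstrap confidence intervals for fixed
    effects, narrow-sense heritability and maternal-effect ratios, and an
    end-to-end reporting and parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
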