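Package: ammistab
Title: AMMI Stability Analysis and Doubled-Haploid Genetic Effects for
    Multi-Environment Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-effects AMMI (additive main effects and multiplicative
    interaction) analysis of balanced genotype-by-environment trials:
    two-way ANOVA, SVD decomposition of the interaction with Gollob
    F-tests for the interaction principal component axes, AMMI stability
    value (ASV) and genotype selection index (GSI), and biplot
    coordinates. Also estimates total additive and additive-by-additive
    (epistatic) gene effects from doubled-haploid line means by the
    quantile method of extreme lines, and provides seeded simulators for
    AMMI trials and doubled-haploid populations. Ships a spring barley
    1000-kernel weight trial (32 genotypes x 6 years) as a worked
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Agroecology, StatisticalMethod, Regression
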