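Package: plumeRecruit
Title: Mixed-Stock Genotype Assignment and Relative Recruitment from River-Plume Nursery Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating relative survival (recruitment) of larval fish
    from distinct nursery habitats to the juvenile stage using multilocus
    codominant (microsatellite) genotypes. Provides GenePop input/output, reference
    population-genetic statistics (Hardy-Weinberg and linkage-disequilibrium
    Monte Carlo tests, Weir-Cockerham F_ST with permutation significance, exact
    tests of allele-frequency differentiation, hierarchical AMOVA), individual
    genotype assignment with Rannala-Mountain Bayesian and frequency-method
    likelihoods (leave-one-out migrant screening, Monte Carlo exclusion tests,
    two-step juvenile assignment with threshold sensitivity sweeps), habitat
    classification from transmissometry, larval abundance ratios with
    observed-versus-expected recruitment chi-square tests, and a synthetic-study
    generator based on the Balding-Nichols model so that every stage of the
    pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
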