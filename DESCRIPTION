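Package: mixformula
Title: Mixture Design, Scheffe Polynomial Modeling and Desirability
    Optimization for Lipid Nanoparticle Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analysing constrained mixture
    experiments on lipid nanoparticle (LNP) formulations. Constructs
    I- and D-optimal designs on a bounded simplex by Fedorov-style
    point exchange over an extreme-vertex candidate set, fits Box-Cox
    power-transformed Scheffe canonical polynomial models to
    formulation responses (encapsulation efficiency, particle
    diameter, normalized median fluorescence intensity), screens terms
    by sequential (type-I) sums of squares and selects models by BIC
    forward selection and backward elimination, computes adequacy
    statistics (predicted R-squared from PRESS, adequate precision),
    and ranks candidate lipid compositions against multiple fitted
    models by weighted Derringer-Suich desirability. Ships the
    four-lipid reference design and fitted response models as built-in
    fixtures together with a synthetic response generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
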