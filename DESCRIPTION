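Package: polyadd
Title: Reversible Step-Growth Polyaddition Kinetics and Flory-Schulz
    Length Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models reversible linear step-growth (polyaddition)
    polymerization of functionally identical monomers, such as
    nonenzymatic RNA oligomerization in well-mixed aqueous solution.
    Provides the equilibrium Flory-Schulz (geometric) chain-length
    distribution and its summary statistics (yield, mass-spectrum mode,
    number-average degree of polymerization, critical concentration),
    the Boltzmann link between bond free energy and bonding probability
    with enthalpy/entropy decomposition, the exact closed-form time
    evolution of the bonding probability, numerical integration of the
    length-truncated mass-action ODE system, a rigorous lower bound on
    the relative error of any mass-conserving truncation together with
    its inversion to a minimum safe truncation length, and utilities for
    interpreting experimental oligomer mass spectra through the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
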