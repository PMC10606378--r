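Package: immunedyn
Title: Equilibria, Stability and Bifurcations of an Immune-Pathogen Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-dimensional deterministic model of the interplay
    between three immunity compartments (innate, humoral, cellular) and a
    replicating pathogen, built from logistic immunity growth and
    Lotka-Volterra-type kill terms. Provides closed-form enumeration of the
    full equilibrium catalogue (15 points for three immunity types,
    2^(n+1)-1 generically), numeric eigenvalue classification, the
    Routh-Hurwitz quartic criterion, analytic characteristic-polynomial
    oracles at the mixed and interior equilibria, transcritical-bifurcation
    surfaces with numerical verification of Sotomayor's conditions, two
    medically motivated control variants with attractor predicates, and
    trajectory simulation with long-run outcome classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
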