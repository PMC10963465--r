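Package: dissectgr
Title: Growth and Remodeling of the Dissected Aortic Membrane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained-mixture growth and remodeling (G&R) analysis of an
    idealized dissected aorta. Builds the idealized dissected-wall geometry,
    evaluates a Holzapfel-Gasser-Ogden elastin/collagen mixture with
    deposition-stretch prestressing, evolves constituent densities and
    collagen remodeling stretches under stress- and inflammation-mediated
    turnover, solves a reduced thick-walled-cylinder equilibrium surrogate for
    the remaining wall and a zero-net-load lamella for the dissected membrane,
    and computes clinical outcome measures (membrane thickening rates, lumen
    diameters and expansion rates, constituent contents). Includes a seeded
    Latin-hypercube parametric study over published growth and remodeling
    parameter ranges with convergence and clinical-range classification and
    parameter-space reduction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lhs,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
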