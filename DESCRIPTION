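Package: ubithresh
Title: Kinetic Models of the EGFR Ubiquitination Threshold
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic kinetic models of early EGF
    receptor signalling at the plasma membrane: multisite tyrosine
    phosphorylation in the free-enzyme regime, cooperative recruitment
    of the Cbl ubiquitin ligase and the Grb2 adaptor to the receptor
    tail, and a mechanistic early-activation layer with conformational
    change, ligand binding and dimerization.  Includes dose-response
    metrics (Hill fits, ubiquitination threshold), local and 10-fold
    sensitivity analyses, simulated-annealing plus simplex parameter
    estimation, a synthetic replicate dose-response generator, and SBML
    round-tripping of the assembled networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
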