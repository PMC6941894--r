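Package: weaklink
Title: Growth, Quantitation, Kinetics and Amplification-Divergence Simulation for Weak-Link Enzyme Evolution Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for laboratory-evolution experiments in which a
    promiscuous "weak-link" enzyme activity limits growth. Estimates specific
    growth rates and generation counts from turbidostat dilution cycles, fits
    modified-Gompertz plate-reader growth curves, performs efficiency-corrected
    qPCR relative quantification against multiple reference genes, computes
    relative fitness from two-colour competition counts, fits burst-phase
    progress curves, Michaelis-Menten and hyperbolic allosteric-effector
    models, and simulates Wright-Fisher dynamics of tandem gene arrays with
    per-copy mutation and recombination-driven allelic sweeps
    (innovation-amplification-divergence dynamics). Includes synthetic-data
    generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
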