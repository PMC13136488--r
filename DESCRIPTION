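Package: rnacircgen
Title: Generative Design of Adaptive Three-Node RNA Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and generative design of small RNA genetic circuits.
    Circuits of three mutually binding RNA species are represented by their six
    pairwise minimum free binding energies, converted to mass-action rates via
    an empirically reparametrised equilibrium constant, and simulated through a
    two-phase step-signal protocol with deSolve. Functional metrics (signal
    sensitivity, precision, a continuous adaptation score) and an evolutionary
    ruggedness statistic are computed from the responses. A conditional
    variational autoencoder trained on (circuit, function) pairs generates
    novel circuits that follow functional prompts; prompt adherence is
    quantified by kernel-density-estimate overlap, precision/recall/F1, and
    hierarchical motif clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
NeedsCompilation: yes
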