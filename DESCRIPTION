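Package: rdassign
Title: Goal-Directed Protein Backbone Assignment from Reduced-Dimensionality NMR
Version: 0.1.0
Authors@R:
    person("rdassign", "authors", email = "rdassign@example.org", role = c("aut", "cre"))
Description: Simulates reduced-dimensionality (tilted-plane) triple-resonance
    NMR data collection for a protein of known sequence and drives an
    iterative, probabilistic backbone resonance assignment engine against it.
    Peaks picked from 2D tilted planes are combined into candidate 3D peaks,
    grouped into probabilistic spin systems anchored to 15N-HSQC peaks, and
    mapped onto the sequence by sum-product inference on a pseudo-energetic
    factor graph with single, pairwise and triple-wise potentials.  An
    information-theoretic planner selects, at every iteration, the next
    experiment and projection angle expected to resolve the weakest links,
    and a termination rule stops collection once assignment completeness and
    secondary-structure determination reach a target quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
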