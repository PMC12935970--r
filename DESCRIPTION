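Package: emisim
Title: Finite-Element Simulation of Coupled Extracellular-Membrane-Intracellular Neural Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the fully coupled EMI (Extracellular-Membrane-Intracellular)
    model of neural electrodynamics: two Poisson problems for the intracellular
    and extracellular potentials joined across an explicit cell membrane by flux
    continuity and a capacitive/ionic membrane equation. Provides structured
    tetrahedral mesh generation for idealized box neurons with tagged membrane
    regions, declarative region-dependent ionic membrane models integrated with
    the Rush-Larsen scheme, first-order operator splitting with a monolithic
    sparse elliptic solve, somatic and extracellular (spherical electrode)
    stimulation protocols, and analysis tools for spike detection, spike-timing
    offsets, ephaptic synchronization, subthreshold oscillation amplitudes and
    open-loop point-source comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
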