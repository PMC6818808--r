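Package: sdspike
Title: Spike-Diffuse-Spike Modelling of Saltatory Conduction in Myelinated Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytic spike-diffuse-spike model of action potential
    propagation along myelinated axons. Nodes of Ranvier release
    threshold-triggered ion channel currents (instantaneous, delayed,
    exponential, or gated multi-exponential profiles) into a passive
    internodal cable; closed-form cable responses built on a numerically
    stable complex error function yield the membrane potential, and a
    safeguarded Newton solve of the implicit threshold condition gives the
    internodal time-to-spike and conduction velocity. Includes parameter
    derivations from electrophysiological constants, sensitivity sweeps over
    axon geometry (diameter, g-ratio, node and internode length), a power-law
    fit of velocity against myelin thickness, unmyelinated-axon velocities,
    and ephaptic coupling between paired fibres with entrainment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
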