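Package: wormcircuit
Title: Fixed-Point Attractor Analysis of C. elegans Neuronal Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links neuronal-circuit structure to function through fixed-point
    attractors. Implements a nonlinear network model of graded membrane
    potentials with sigmoidal chemical synapses and ohmic gap junctions,
    multi-start Newton root finding with Jacobian-eigenvalue stability
    classification, bifurcation sweeps over connection strength, screening of
    connectomes for bistability-capable motifs and excitatory positive
    feedback loops, Monte-Carlo estimation of attraction domains, an
    attractor-based finite state machine driven by stimulus protocols,
    in-silico neuron ablation and gap-junction removal screens, and analysis
    of locomotion speed traces (sign-based segmentation, bimodal Gaussian
    fits, event statistics) with a matched synthetic trace generator. Ships a
    ten-neuron command-interneuron circuit (AVA, AVB, AVD, AVE, PVC pairs)
    whose three attractors correspond to forward, backward and quiescent
    locomotor states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
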