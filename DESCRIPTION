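Package: eiann
Title: Biology-Constrained Excitatory-Inhibitory Networks with Dendritic
    Target Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and train multilayer recurrent rate networks whose units
    are partitioned into excitatory and inhibitory cell types with
    sign-constrained synapses (Dale's law), and whose excitatory units carry
    separate soma and apical-dendrite compartments.  Implements the dendritic
    target propagation learning algorithm, in which a supervisory nudge at
    the output layer is relayed top-down into hidden-layer dendrites, where
    a locally computed error (top-down excitation minus learned lateral
    inhibition) gates synaptic plasticity.  Ships a family of biologically
    motivated learning rules (linear dendritic-state rule, behavioral
    timescale synaptic plasticity with eligibility traces, temporally
    contrastive Hebbian, BCM with a sliding threshold, normalized Hebbian,
    and a learned top-down projection), truncated
    backpropagation-through-time baselines, a seeded 2D-spirals task
    generator plus an MNIST IDX reader, and an analysis suite (accuracy,
    stimulus selectivity, Moran's I, gradient receptive fields, and
    weight-update alignment angles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    nnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
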