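# eiann

Biology-constrained deep learning in R: multilayer recurrent rate networks
with separate excitatory and inhibitory cell types (Dale's law), separate
soma/dendrite compartments in excitatory neurons, and the **dendritic
target propagation** learning algorithm, in which credit assignment is
computed locally in apical dendrites as the difference between top-down
excitation and learned lateral inhibition.

The package is aimed at computational neuroscientists who want to study
how biologically documented plasticity mechanisms — behavioral-timescale
synaptic plasticity (BTSP), temporally contrastive Hebbian learning,
BCM-style sliding thresholds, heterosynaptic weight normalization — can be
assembled into a working multilayer learning system, and how close each
comes to gradient descent.

## The model in brief

Each layer holds excitatory cells (E) plus soma-targeting (SomaI) and
dendrite-targeting (DendI) interneurons.  Somatic states follow leaky
discrete-time dynamics (time constant `tau = 3`, 15 steps per phase):

    tau * ds = -s + W a_below + Y a_SomaI         (E somata)
    d        =  B a_above + Y_dend a_DendI        (E apical dendrites)
    a        =  relu(s + beta) + d * 1[s + beta > 0]

A trial has two phases: a *sensory* equilibration under the stimulus, then
a supervisory nudge `N = T - A` applied to output dendrites, propagated
top-down (clipped to [-1, 1]), and a *supervised* re-equilibration with
dendritic states frozen.  Because DendI inhibition learns
(`dY = -eta * d * a`) to cancel the predictable top-down drive during the
sensory phase, the nudged dendritic state `dhat` approximates the local
error gradient, and the bottom-up update

    dW[i,j] = eta * dhat_i * gate_i * a_j

approximates backpropagation while every synapse keeps its sign.

## Worked example

Train a small dendritic network on the built-in four-class spiral task and
compare its weight updates to the gradient:

```r
library(eiann)

train <- generate_spirals(1400, n_classes = 4, seed = 1)
val   <- generate_spirals(300, n_classes = 4, seed = 1,
                          split = "validation")

net <- spirals_network("dendritic_lds", seed = 1)
net <- center_biases(net, colMeans(train$inputs))

res <- train_network(net, train, epochs = 1, seed = 1)
evaluate_accuracy(res$net, val)
#> [1] 35.66667

cmp <- compare_to_backprop(res$net, train, samples = 1:5)
aggregate(angle ~ projection + comparison, cmp, mean)
#>   projection         comparison        angle
#> 1     E2->E1            B_vs_Wt 8.537736e-07
#> 2     E3->E2            B_vs_Wt 0.000000e+00
#> 3     E1->E2 update_vs_gradient 4.421417e+00
#> 4     E2->E3 update_vs_gradient 6.147200e-01
#> 5  Input->E1 update_vs_gradient 4.028104e+01
```

`evaluate_accuracy` reports percent of validation samples whose most
active output unit matches the label (chance is 25%; shipped
hyperparameters come from a coarse search, so absolute accuracy is well
below the ceiling of the task — see the vignette's limitations section).
The angles are the more informative readout here: per projection, they
show how far the dendritic rule's prescribed update is from the
truncated-backpropagation update on the same stimuli (0 degrees =
identical direction) — the upper-layer updates are nearly parallel to the
gradient — and that the symmetric top-down weights equal the bottom-up
transpose.

A command-line wrapper with `generate-data`, `train`, `evaluate` and
`inspect` subcommands ships in `inst/scripts/eiann`; network architectures
are declared in YAML (`inst/extdata/dendritic_tiny.yaml` documents the
schema).

## Learning rules

| rule id        | drives plasticity with                     |
|----------------|--------------------------------------------|
| `lds`          | nudged dendritic state x gate x presyn act |
| `btsp`         | eligibility traces x instructive signals, saturable, cross-stimulus decay |
| `tch`          | supervised-minus-sensory activity products |
| `bcm`          | supervised products gated by a sliding threshold |
| `hebb_norm`    | activity correlation + per-row normalization |
| `dend_inhib`   | dendritic state x DendI activity (cancellation) |
| `topdown_tch`  | temporal contrast, learns top-down B with normalization |
| `backprop`     | truncated backprop-through-time baseline |
| `backprop_local` | gradient of each layer's mean squared dendritic state |

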