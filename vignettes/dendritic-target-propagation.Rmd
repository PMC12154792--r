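---
title: "Dendritic target propagation in excitatory-inhibitory rate networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic target propagation in excitatory-inhibitory rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiann)
```

## The model

`eiann` simulates multilayer rate networks whose units are split into
excitatory (E) and inhibitory cell types with sign-constrained synapses
(Dale's law), and whose excitatory units carry two compartments: a soma and
an apical dendrite.  Within each layer, E cells and soma-targeting
interneurons (SomaI) receive bottom-up excitation from the layer below;
SomaI cells inhibit the somata of their layer's E cells and each other,
forming the feedforward/feedback inhibitory motifs of cortical and
hippocampal circuits.  Dendrite-targeting interneurons (DendI) receive
lateral excitation and recurrent inhibition, and inhibit the apical
dendrites of their layer's E cells.

Somatic states integrate with a leak:

    tau * ds_i[t] = -s_i[t-1] + (bottom-up drive)[t] + (lateral drive)[t-1]

with `tau = 3` and layers swept bottom to top inside one synchronous time
step, so bottom-up terms use the current step's lower-layer activities
while every lateral, recurrent and top-down term uses the previous step.
This is the only update schedule consistent with the time indices of the
somatic-state equations: a stimulus propagates one layer per step upward,
while all within-layer and downward interactions are delayed by one step.
Activities are rectified-linear, `a = f(s + beta)`, and the apical
dendrite adds its state through the somatic gate:
`a = f(s + beta) + d * g`, where `g = 1` exactly when `s + beta > 0`
(strictly; a unit at threshold is closed).

The dendritic state of a hidden E cell is the sum of top-down excitation
from the layer above (weights `B`) and lateral DendI inhibition (weights
`Y`), recomputed each step from the previous step's activities.  During
stimulus presentation ("sensory phase", 15 steps from rest) the output
layer's dendrites are clamped to zero.

## The two-phase trial and the learning rules

After sensory equilibration, a supervisory nudge `N = T - A` is applied to
the output dendrites (`T` the one-hot target), and nudged dendritic states
are propagated top-down in a single sweep: each hidden layer's nudged
dendritic state combines the top-down drive from the already-nudged layer
above with the *sensory-phase* DendI inhibition, and is clipped to
[-1, 1].  Because the dendritic-inhibition rule

    dy_ik = -eta_Y * d_i * a_k          (sensory-phase d and a)

tunes the inhibition to cancel the *expected* (sensory) top-down drive,
the un-cancelled remainder after the nudge approximates the layer's local
error.  The nudged states are then frozen while the somata re-equilibrate
for another 15 steps ("supervised phase").

Bottom-up weights can then be updated by any of:

* **LDS** (linear dendritic-state rule): `dw = eta * dhat_i * g_i * a_j`,
  the direct gradient-like rule;
* **BTSP**: a saturable bidirectional rule driven by presynaptic
  eligibility traces and postsynaptic instructive signals, with
  cross-stimulus decay `lambda` and a weight-dependence that potentiates
  weak synapses toward `w_max` and depresses strong ones (the saturating
  sigmoid meets `sigma(0) = 0`, `sigma(1) = 1`); rows with negative nudged
  dendritic state fall back to LDS;
* **TCH**: the difference of activity correlations between the supervised
  and sensory phases;
* **BCM**: supervised-phase Hebbian terms gated by a sliding threshold
  `theta` that tracks recent squared activity (`theta <- theta +
  (-theta + a^2/k) / tau_theta`);
* **normalized Hebbian**: correlation-proportional growth followed by
  rescaling each neuron's incoming weight magnitudes to a fixed total
  (heterosynaptic normalization);
* truncated **backpropagation** baselines (below).

Excitatory biases, when enabled, follow `dbeta = eta_beta * dhat * g`.
Top-down weights are either slaved to the bottom-up transpose
(`B = b_scale * t(W)`), frozen at random values (feedback-alignment
control), or learned with the temporally contrastive rule plus per-neuron
normalization to `b_sum`.

All deltas for one stimulus are computed from the frozen trial record and
applied atomically; sign constraints, zero recurrent diagonals and BTSP
weight bounds are re-imposed after every update, and normalization is
applied after the additive step, as the rescaling formulas prescribe.

## Gradient baselines and alignment analyses

The backpropagation baseline differentiates the mean squared output error
through exactly the last 3 integration steps of the sensory phase, with
the state at the window start treated as constant (truncated
backpropagation through time).  The reverse pass is hand-written and is
verified in the test suite against central finite differences of the
truncated forward computation (relative error below 1e-4; in practice
~1e-8).  The same machinery provides the local baseline that trains DendI
inputs by descending each layer's mean squared dendritic state, gradient
receptive fields (the gradient of a unit's equilibrated activity with
respect to the input, averaged over stimuli and normalized), and the
alignment-angle analyses: the angle between a rule's update and the
gradient update, and between `B` and `t(W)`.

In the idealized limit — no lateral projections, symmetric `B`, exact
dendritic cancellation, gates at their sensory values, small nudge — the
nudged dendritic state equals the backpropagated error and the LDS update
is parallel to the gradient; the suite asserts cosine similarity at least
0.999 over 20 seeded fixtures.  The analogous TCH property is weaker: the
temporal contrast recovers the dendritic term plus first-order
presynaptic cross-terms, so the TCH-LDS angle decreases with nudge scale
but converges to a small positive value rather than zero.  The suite
asserts the monotone decrease of the seed-averaged angle.

## The spirals task and the synthetic-data generator

The four-class 2D spiral generator places class `c` on the arm
`(r cos(phi + 2 pi c / 4), r sin(phi + 2 pi c / 4))` with radius
proportional to angle, maps coordinates into the unit box, and adds
Gaussian coordinate noise.  Defaults are `turns = 0.5` and
`noise_sd = 0.03`; they were fixed once, before training the
biological networks, by an independent calibration: an unconstrained
2-128-32-4 ReLU reference network trained with the same protocol
(mean-squared error, batch size 1, one epoch of 5,600 samples) must solve
the task (~94% validation accuracy), while a multinomial linear readout
must stay well below 70% (~53%), so the benchmark is genuinely nonlinear
but learnable in a single epoch.  With more turns or more noise the
reference network itself fails under this protocol, which would make every
biological comparison vacuous.  The generator is a pure function of its
parameters and seed; train/validation splits use distinct substreams.

What the generator does *not* emulate: high-dimensional inputs, input
correlations of natural images, class imbalance, or label noise.  Passing
the spirals experiments therefore demonstrates credit assignment through
depth and nonlinearity, not robustness to realistic sensory statistics;
the MNIST IDX reader supports full-scale runs when local files are
supplied.

## Numerical choices and degenerate inputs

* Uniform weight initialization on `[0, w_init/n_pre]`, one named random
  substream per projection, so adding a projection never perturbs the
  others.
* Excitatory thresholds can be centered at the operating point
  (`center_biases()`): with all-positive inputs and sign-constrained
  weights, zero-initialized biases leave every rectifier permanently open
  and the network exactly linear; centering breaks this degeneracy the
  way background inhibition and intrinsic thresholds do in biological
  circuits.
* The dendritic bound (clip at +/-1) is applied to nudged states only,
  including the output layer, for uniformity across layers.
* Nudged activities are not re-rectified (`clamp_activity_nonneg`
  defaults off): a strongly negative nudged dendritic state may produce a
  negative activity, as the nudge equation permits.
* Divergence guard: any somatic state beyond 1e6 aborts the trial with an
  instability error naming the populations involved.
* Normalization rules leave all-zero rows unchanged (with a warning)
  rather than dividing by zero; the BCM scale `k` and BTSP bound `w_max`
  must be positive.
* Ties in the accuracy argmax resolve to the lowest unit index.

## Problem sizes used by the test suite

Unit and property tests run on fixtures with at most 10 units per
population.  The end-to-end spirals experiments use the full
2/128-32-4 architecture with 54 and 13 dendrite-targeting interneurons,
5,600 training samples for one epoch and 1,200 validation samples,
averaged over 5 seeded instances; the top-down-learning comparison reuses
the same architecture at a reduced sample count per seed.  These sizes
resolve the phenomena of interest (nonlinear classification, bias
dependence, weight-symmetry dynamics) while keeping the default test run
in the minutes range on a single core.

## Known limitations

* Hyperparameters ship as fixed defaults obtained by a coarse random
  search on the spirals fixture; the original large-scale population
  search is out of scope, so absolute accuracies are not tuned to their
  ceiling.  Under the shipped defaults the sign-constrained networks
  clear the bias-dependence contrast (the bias-enabled network beats the
  bias-disabled one, which stays at chance) but remain far below the
  unconstrained reference network on the same protocol: with
  all-positive weights, the constrained credit-assignment problem is
  acutely sensitive to the balance between excitation, inhibition and
  thresholds, which is precisely what the original large search tuned.
  The update-direction analyses (cosine alignment with the gradient) are
  the robust, hyperparameter-insensitive results of this package.
* One dendritic compartment per cell; no spiking, bursting, or
  conductance-based dynamics.
* The nudge propagates in a single top-down sweep per trial; schedules
  interleaving sensory and supervisory input continuously are not
  modeled.
* Output-layer SomaI units receive no top-down input (none is specified
  for them), and biases are excluded from weight normalization.
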