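# Small dendritic architecture used by the oracle tests: two hidden layers
# of excitatory cells with soma- and dendrite-targeting interneurons,
# symmetric top-down weights, LDS-bound bottom-up projections.
tau: 3
steps_per_phase: 15
dendrite_clip: 1
symmetric_b: true
b_scale: 0.5
populations:
  - {name: Input, layer: 0, type: Input, size: 3}
  - {name: E1, layer: 1, type: E, size: 6, dendrite: true, bias: true, eta_bias: 0.05}
  - {name: SomaI1, layer: 1, type: SomaI, size: 3}
  - {name: DendI1, layer: 1, type: DendI, size: 3}
  - {name: E2, layer: 2, type: E, size: 5, dendrite: true, bias: true, eta_bias: 0.05}
  - {name: SomaI2, layer: 2, type: SomaI, size: 2}
  - {name: DendI2, layer: 2, type: DendI, size: 2}
  - {name: E3, layer: 3, type: E, size: 4, dendrite: true}
  - {name: SomaI3, layer: 3, type: SomaI, size: 2}
projections:
  - {pre: Input, post: E1, direction: "W", w_init: 2, rule: lds, eta: 0.1}
  - {pre: Input, post: SomaI1, direction: "W", w_init: 0.5}
  - {pre: SomaI1, post: E1, direction: "Y", sign: -1, w_init: 0.5}
  - {pre: E1, post: SomaI1, direction: "Q", w_init: 0.5}
  - {pre: SomaI1, post: SomaI1, direction: "R", sign: -1, w_init: 0.25}
  - {pre: E1, post: DendI1, direction: "Q", w_init: 0.5, rule: hebb_norm, eta: 0.05, norm_total: 1}
  - {pre: DendI1, post: DendI1, direction: "R", sign: -1, w_init: 0.25}
  - {pre: DendI1, post: E1, direction: "Y", sign: -1, target: dendrite, w_init: 0.5, rule: dend_inhib, eta: 0.05}
  - {pre: E2, post: E1, direction: "B", target: dendrite, w_init: 0.5}
  - {pre: E1, post: E2, direction: "W", w_init: 2, rule: lds, eta: 0.1}
  - {pre: E1, post: SomaI2, direction: "W", w_init: 0.5}
  - {pre: SomaI2, post: E2, direction: "Y", sign: -1, w_init: 0.5}
  - {pre: E2, post: SomaI2, direction: "Q", w_init: 0.5}
  - {pre: SomaI2, post: SomaI2, direction: "R", sign: -1, w_init: 0.25}
  - {pre: E2, post: DendI2, direction: "Q", w_init: 0.5, rule: hebb_norm, eta: 0.05, norm_total: 1}
  - {pre: DendI2, post: DendI2, direction: "R", sign: -1, w_init: 0.25}
  - {pre: DendI2, post: E2, direction: "Y", sign: -1, target: dendrite, w_init: 0.5, rule: dend_inhib, eta: 0.05}
  - {pre: E3, post: E2, direction: "B", target: dendrite, w_init: 0.5}
  - {pre: E2, post: E3, direction: "W", w_init: 2, rule: lds, eta: 0.1}
  - {pre: E2, post: SomaI3, direction: "W", w_init: 0.5}
  - {pre: SomaI3, post: E3, direction: "Y", sign: -1, w_init: 0.5}
  - {pre: E3, post: SomaI3, direction: "Q", w_init: 0.5}
  - {pre: SomaI3, post: SomaI3, direction: "R", sign: -1, w_init: 0.25}
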