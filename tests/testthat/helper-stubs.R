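# Hand-crafted trial records for exercising learning rules in isolation:
# every field defaults to zeros (gates to open) and named vectors override
# per population.

stub_trial <- function(net, sens_A = list(), sens_D = list(),
                       sens_G = list(), sup_A = list(), dhat = list()) {
  plan <- net$plan
  mk <- function(vals, default = 0) {
    out <- lapply(plan$sizes, function(n) rep(default, n))
    for (nm in names(vals)) out[[plan$idx[[nm]]]] <- vals[[nm]]
    out
  }
  structure(list(
    sens = list(S = mk(list()), A = mk(sens_A), D = mk(sens_D),
                G = mk(sens_G, 1)),
    sup = list(S = mk(list()), A = mk(sup_A), G = mk(list(), 1)),
    dhat = dhat), class = "eiann_trial")
}

# Minimal one-synapse network: Input(n_pre) -> E1(n_post), E1 dendritic.
pair_net <- function(n_pre = 1, n_post = 1, rule = "lds", eta = 0.1, ...) {
  build_network(
    list(population("Input", 0, "Input", n_pre),
         population("E1", 1, "E", n_post, dendrite = TRUE)),
    list(projection("Input", "E1", "W", rule = rule, eta = eta, ...)))
}
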