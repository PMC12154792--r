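# Straight-line oracle for the two-phase trial protocol on a small
# one-hidden-layer dendritic network, written independently of the package
# internals: explicit named matrices, plain loops, literal update formulas.

# Builds a 2-2-2 dendritic network (Input 2; E1 2 + DendI1 1; E2 2) with
# fixed random weights and no somatic interneurons.
oracle_net <- function(seed = 1, exact_cancellation = FALSE, b_scale = 0.8,
                       nudge_scale = 1) {
  pops <- list(
    population("Input", 0, "Input", 2),
    population("E1", 1, "E", 2, dendrite = TRUE),
    population("DendI1", 1, "DendI", 1),
    population("E2", 2, "E", 2, dendrite = TRUE))
  projs <- list(
    projection("Input", "E1", "W", w_init = 2),
    projection("E1", "DendI1", "Q", w_init = 1),
    projection("DendI1", "E1", "Y", sign = -1, target = "dendrite",
               w_init = 1),
    projection("E2", "E1", "B", target = "dendrite", w_init = 1),
    projection("E1", "E2", "W", w_init = 2))
  build_network(pops, projs, seed = seed, symmetric_b = TRUE,
                b_scale = b_scale, exact_cancellation = exact_cancellation,
                nudge_scale = nudge_scale)
}

# Plain-loop simulation of one full trial on oracle_net(): sensory phase,
# nudge, top-down propagation, supervised phase.  Returns snapshots in the
# same shapes as run_trial for comparison.
oracle_trial <- function(net, x, target, steps = net$cfg$steps_per_phase,
                         tau = net$cfg$tau) {
  W1 <- get_weights(net, "Input->E1")
  Q <- get_weights(net, "E1->DendI1")
  Y <- get_weights(net, "DendI1->E1")
  B <- get_weights(net, "E2->E1")
  W2 <- get_weights(net, "E1->E2")
  f <- function(z) pmax(z, 0)
  fp <- function(z) as.numeric(z > 0)
  exact <- net$cfg$exact_cancellation

  s1 <- c(0, 0); s2 <- c(0, 0); sd_ <- 0
  a1 <- c(0, 0); a2 <- c(0, 0); ad <- 0
  d1 <- c(0, 0)
  for (t in seq_len(steps)) {
    a1_prev <- a1; a2_prev <- a2; ad_prev <- ad
    d1 <- if (exact) c(0, 0) else
      as.vector(B %*% a2_prev) + as.vector(Y %*% ad_prev)
    s1 <- s1 + (-s1 + as.vector(W1 %*% x)) / tau
    a1 <- f(s1) + d1 * fp(s1)
    sd_ <- sd_ + (-sd_ + as.vector(Q %*% a1_prev)) / tau
    ad <- f(sd_)
    s2 <- s2 + (-s2 + as.vector(W2 %*% a1)) / tau
    a2 <- f(s2)                       # output dendrite clamped to zero
  }
  N <- net$cfg$nudge_scale * (target - a2)
  clip <- function(v) pmin(pmax(v, -net$cfg$dendrite_clip),
                           net$cfg$dendrite_clip)
  dhat2 <- clip(N)
  ahat2 <- f(s2) + dhat2 * fp(s2)
  dhat1 <- as.vector(B %*% ahat2) +
    (if (exact) -as.vector(B %*% a2) else as.vector(Y %*% ad))
  dhat1 <- clip(dhat1)
  ahat1 <- f(s1) + dhat1 * fp(s1)

  st1 <- s1; st2 <- s2; std <- sd_
  at1 <- a1; at2 <- a2; atd <- ad
  for (t in seq_len(steps)) {
    at1_prev <- at1; atd_prev <- atd
    st1 <- st1 + (-st1 + as.vector(W1 %*% x)) / tau
    at1 <- f(st1) + dhat1 * fp(st1)
    std <- std + (-std + as.vector(Q %*% at1_prev)) / tau
    atd <- f(std)
    st2 <- st2 + (-st2 + as.vector(W2 %*% at1)) / tau
    at2 <- f(st2) + dhat2 * fp(st2)
  }
  list(sens = list(s1 = s1, a1 = a1, d1 = d1, s2 = s2, a2 = a2, ad = ad),
       N = N, dhat1 = dhat1, dhat2 = dhat2, ahat1 = ahat1, ahat2 = ahat2,
       sup = list(s1 = st1, a1 = at1, s2 = st2, a2 = at2, ad = atd))
}

# Convenience accessors for package state lists.
pv <- function(net, st, pop, field = "A") st[[field]][[net$plan$idx[[pop]]]]
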