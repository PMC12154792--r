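# Two-phase trial protocol: sensory equilibration, output nudge, top-down
# propagation of nudged dendritic states, supervised re-equilibration.

#' Compute the supervisory nudge at the output layer
#'
#' The nudge is the signed output error `N = T - A` (optionally scaled),
#' and becomes the nudged dendritic state of the output layer after
#' clipping to the dendritic bound.
#'
#' @param a_out output-layer excitatory activity vector.
#' @param target one-hot target vector of the same length.
#' @param scale nudge scale (1 = full supervisory signal).
#' @param clip dendritic-state bound.
#' @return list with `N` (raw nudge) and `dhat` (clipped output dendritic
#'   state).
#' @export
output_nudge <- function(a_out, target, scale = 1, clip = 1) {
  if (length(a_out) != length(target))
    stop("output activity and target lengths differ")
  if (!isTRUE(all.equal(sort(unique(target)), c(0, 1))) ||
      sum(target == 1) != 1)
    stop("target must be a one-hot vector")
  N <- scale * (target - a_out)
  list(N = N, dhat = pmin(pmax(N, -clip), clip))
}

#' Nudge activities given frozen dendritic states
#'
#' Applies `A_hat = relu(s) + dhat * gate(s)` elementwise: the dendritic
#' state perturbs the firing rate only where the somatic gate is open.
#'
#' @param s somatic state vector (bias already included, if any).
#' @param dhat nudged dendritic state vector.
#' @param g optional gate vector; recomputed from `s` when missing.
#' @param clamp_nonneg clip the result at zero from below.
#' @return nudged activity vector.
#' @export
nudge_activities <- function(s, dhat, g = NULL, clamp_nonneg = FALSE) {
  if (is.null(g)) g <- relu_gate(s)
  a <- relu(s) + dhat * g
  if (clamp_nonneg) a <- pmax(a, 0)
  a
}

#' Propagate the output nudge into hidden-layer dendrites
#'
#' Starting from the output layer and proceeding downward one layer at a
#' time, each hidden layer's nudged dendritic state is the top-down drive
#' from the (already nudged) layer above plus the sensory-phase
#' dendrite-targeting inhibition, clipped to the dendritic bound.  Because
#' the inhibition was tuned during the sensory phase to cancel the sensory
#' top-down drive, the surviving signal approximates the layer's local
#' error.  The sweep is a single top-down pass; each layer's `dhat` is
#' frozen once computed.
#'
#' @param net an `eiann_network`.
#' @param sens sensory-phase state (from [equilibrate()]).
#' @param dhat_out clipped output-layer nudged dendritic state.
#' @return list with `dhat` and `ahat`, named lists over dendritic E
#'   populations (output included).
#' @export
propagate_nudge <- function(net, sens, dhat_out) {
  plan <- net$plan
  clip <- net$cfg$dendrite_clip
  e_pops <- names(net$pops)[plan$types == "E" & plan$dendritic]
  e_layers <- plan$layers[e_pops]
  out_pop <- e_pops[e_layers == net$L]
  if (length(out_pop) != 1) stop("expected one dendritic output E population")

  dhat <- list(); ahat <- list()
  dhat[[out_pop]] <- dhat_out
  z_out <- sens$S[[plan$idx[[out_pop]]]] + plan$bias[[plan$idx[[out_pop]]]]
  ahat[[out_pop]] <- nudge_activities(z_out, dhat_out,
                                      clamp_nonneg = net$cfg$clamp_activity_nonneg)

  for (l in sort(unique(e_layers[e_layers < net$L]), decreasing = TRUE)) {
    pop <- e_pops[e_layers == l]
    upper <- e_pops[e_layers == l + 1]
    pi_ <- plan$idx[[pop]]
    bname <- find_projection(net, pre = upper, post = pop, direction = "B")
    if (is.null(bname))
      stop("dendritic population ", pop, " lacks a top-down B projection")
    B <- net$projs[[bname]]$W
    d <- as.vector(B %*% ahat[[upper]])
    if (net$cfg$exact_cancellation) {
      d <- d - as.vector(B %*% sens$A[[plan$idx[[upper]]]])
    } else {
      yname <- find_projection(net, post = pop, direction = "Y",
                               target = "dendrite")
      if (!is.null(yname)) {
        p <- net$projs[[yname]]
        d <- d + as.vector(p$W %*% sens$A[[plan$idx[[p$pre]]]])
      }
    }
    d <- pmin(pmax(d, -clip), clip)
    dhat[[pop]] <- d
    z <- sens$S[[pi_]] + plan$bias[[pi_]]
    ahat[[pop]] <- nudge_activities(z, d, sens$G[[pi_]],
                                    clamp_nonneg = net$cfg$clamp_activity_nonneg)
  }
  list(dhat = dhat, ahat = ahat)
}

#' Run one two-phase trial
#'
#' (1) Sensory phase: equilibrate from rest under the stimulus with the
#' output dendrites clamped to zero.  (2) Nudge: compute the output nudge
#' from the one-hot target and propagate it top-down into hidden dendrites.
#' (3) Supervised phase: hold all nudged dendritic states constant and
#' re-equilibrate the somatic states.  No weights are modified; the
#' returned record is the immutable input to every learning rule.
#'
#' @param net an `eiann_network`.
#' @param stimulus input vector.
#' @param target one-hot target vector over output E units.
#' @param retain_history keep per-step states of both phases (needed for
#'   the backpropagation-through-time baseline).
#' @param supervised run the supervised re-equilibration phase; rules that
#'   only read the sensory snapshot and the nudged dendritic states (LDS,
#'   dendritic inhibition, sensory-phase Hebbian) do not require it, and
#'   the training loop skips it when no bound rule does.
#' @return a `trial_record`: stimulus, target, `N`, sensory snapshot
#'   (`sens`), nudged states (`dhat`, `ahat`), supervised snapshot (`sup`;
#'   `NULL` when skipped), oscillation residuals, and optional histories.
#' @export
run_trial <- function(net, stimulus, target, retain_history = FALSE,
                      supervised = TRUE) {
  weights <- lapply(net$projs, `[[`, "W")
  sens_eq <- equilibrate(net, stimulus, state = NULL,
                         retain_history = retain_history, weights = weights)
  sens <- sens_eq$state

  plan <- net$plan
  out_pop <- names(net$pops)[plan$types == "E" & plan$layers == net$L]
  a_out <- sens$A[[plan$idx[[out_pop]]]]
  nud <- output_nudge(a_out, target, scale = net$cfg$nudge_scale,
                      clip = net$cfg$dendrite_clip)

  if (isTRUE(net$pops[[out_pop]]$dendrite)) {
    prop <- propagate_nudge(net, sens, nud$dhat)
  } else {
    prop <- list(dhat = stats::setNames(list(nud$dhat), out_pop),
                 ahat = stats::setNames(list(nudge_activities(
                   sens$S[[plan$idx[[out_pop]]]] + plan$bias[[plan$idx[[out_pop]]]],
                   nud$dhat, sens$G[[plan$idx[[out_pop]]]],
                   clamp_nonneg = net$cfg$clamp_activity_nonneg)), out_pop))
  }

  sup_eq <- if (supervised)
    equilibrate(net, stimulus, state = sens, dhat = prop$dhat,
                retain_history = retain_history, weights = weights)
  else list(state = NULL, residual = NA_real_, history = NULL)

  structure(list(stimulus = stimulus, target = target, N = nud$N,
                 sens = sens, dhat = prop$dhat, ahat = prop$ahat,
                 sup = sup_eq$state,
                 residual_sensory = sens_eq$residual,
                 residual_supervised = sup_eq$residual,
                 history = sens_eq$history,
                 sup_history = sup_eq$history),
            class = "eiann_trial")
}
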