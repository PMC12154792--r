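# Truncated backpropagation through time (BPTT) over the recurrent
# dynamics.  The forward pass is the ordinary equilibration; the reverse
# pass unrolls the last k integration steps, treating the state at the
# start of the window as constant.  Used for the gradient-descent baseline
# (global mean-squared output error), for gradient-trained dendritic
# inhibition (per-layer mean-squared dendritic state), and for gradient
# receptive fields.

# Reverse-mode pass.  history is the list of states recorded by
# equilibrate(retain_history = TRUE); seeds are gradients of the objective
# with respect to final-step activities (seed_A) and/or dendritic states
# (seed_D), as named lists over populations.
bptt_grads <- function(net, history, k = 3, seed_A = NULL, seed_D = NULL) {
  plan <- net$plan
  TT <- length(history)
  if (TT < k + 1) stop("history too short for a ", k, "-step backward pass")
  rho <- 1 - 1 / net$cfg$tau
  inv_tau <- 1 / net$cfg$tau
  Wl <- lapply(net$projs, `[[`, "W")
  gW <- lapply(Wl, function(w) array(0, dim(w)))
  g_in <- numeric(plan$sizes[[plan$input]])
  g_bias <- lapply(plan$sizes, numeric)

  zero <- lapply(plan$sizes, numeric)
  gS <- gA <- gD <- vector("list", TT)
  for (t in (TT - k):TT) { gS[[t]] <- zero; gA[[t]] <- zero; gD[[t]] <- zero }
  for (nm in names(seed_A)) {
    i <- plan$idx[[nm]]
    gA[[TT]][[i]] <- gA[[TT]][[i]] + seed_A[[nm]]
  }
  for (nm in names(seed_D)) {
    i <- plan$idx[[nm]]
    gD[[TT]][[i]] <- gD[[TT]][[i]] + seed_D[[nm]]
  }

  rev_order <- rev(plan$update_order)
  for (t in TT:(TT - k + 1)) {
    st <- history[[t]]
    stp <- history[[t - 1]]
    for (pi_ in rev_order) {
      dend_active <- plan$dendritic[[pi_]] && plan$layers[[pi_]] < net$L &&
        !net$cfg$exact_cancellation
      # activity node: a = relu(z) + d * gate(z)
      ga <- gA[[t]][[pi_]]
      if (any(ga != 0)) {
        g <- st$G[[pi_]]
        gS[[t]][[pi_]] <- gS[[t]][[pi_]] + ga * g
        g_bias[[pi_]] <- g_bias[[pi_]] + ga * g
        if (dend_active) gD[[t]][[pi_]] <- gD[[t]][[pi_]] + ga * g
      }
      # dendrite node: d[t] = sum_j W_j a_pre[t-1]
      if (dend_active) {
        gd <- gD[[t]][[pi_]]
        if (any(gd != 0)) {
          for (j in plan$dend_prev[[pi_]]) {
            pre <- plan$proj_pre[j]
            gW[[j]] <- gW[[j]] + outer(gd, stp$A[[pre]])
            gA[[t - 1]][[pre]] <- gA[[t - 1]][[pre]] +
              as.vector(crossprod(Wl[[j]], gd))
          }
        }
      }
      # soma node: s[t] = rho * s[t-1] + (1/tau) * drive
      gs <- gS[[t]][[pi_]]
      if (any(gs != 0)) {
        gS[[t - 1]][[pi_]] <- gS[[t - 1]][[pi_]] + rho * gs
        for (j in plan$soma_cur[[pi_]]) {
          pre <- plan$proj_pre[j]
          gW[[j]] <- gW[[j]] + inv_tau * outer(gs, st$A[[pre]])
          back <- inv_tau * as.vector(crossprod(Wl[[j]], gs))
          if (pre == plan$input) g_in <- g_in + back
          else gA[[t]][[pre]] <- gA[[t]][[pre]] + back
        }
        for (j in plan$soma_prev[[pi_]]) {
          pre <- plan$proj_pre[j]
          gW[[j]] <- gW[[j]] + inv_tau * outer(gs, stp$A[[pre]])
          back <- inv_tau * as.vector(crossprod(Wl[[j]], gs))
          if (pre == plan$input) g_in <- g_in + back
          else gA[[t - 1]][[pre]] <- gA[[t - 1]][[pre]] + back
        }
      }
    }
  }
  list(W = stats::setNames(gW, names(net$projs)), input = g_in,
       bias = stats::setNames(g_bias, names(net$pops)))
}

# Run k dynamics steps from a fixed start state (the truncated objective
# differentiated by bptt_grads); used by the finite-difference oracle.
truncated_forward <- function(net, start_state, input, k,
                              weights = NULL) {
  state <- start_state
  for (t in seq_len(k))
    state <- step_dynamics(net, state, input, weights = weights)
  state
}

#' Backpropagation baseline gradients
#'
#' Computes gradient-descent reference updates by backpropagating through
#' the last `k` equilibration time steps of the sensory phase (the state
#' at the start of the window is treated as constant).
#'
#' Mode `"global_mse"` differentiates the global loss
#' `L = (1/n) * sum((t_i - a_i)^2)` over output excitatory activities.
#' Mode `"local_dendritic"` differentiates, within each hidden layer, the
#' local loss `L(l) = (1/n) * sum(d_i^2)` over that layer's excitatory
#' dendritic states, returning gradients only for the projections onto the
#' layer's dendrite-targeting interneurons (their lateral excitatory and
#' recurrent inhibitory inputs).
#'
#' @param trial a trial record from [run_trial()] with
#'   `retain_history = TRUE`.
#' @param net the network.
#' @param mode `"global_mse"` or `"local_dendritic"`.
#' @param k truncation window in time steps.
#' @return list with `W` (named list of gradient matrices; multiply by
#'   `-eta` for a descent update), `input` (gradient with respect to the
#'   input vector, global mode), and `loss` (the objective value).
#' @export
backprop_baseline <- function(trial, net, mode = c("global_mse", "local_dendritic"),
                              k = 3) {
  mode <- match.arg(mode)
  if (is.null(trial$history))
    stop("trial was run without retain_history = TRUE")
  plan <- net$plan
  if (mode == "global_mse") {
    out_pop <- names(net$pops)[plan$types == "E" & plan$layers == net$L]
    a_out <- trial$sens$A[[plan$idx[[out_pop]]]]
    n <- length(a_out)
    seed <- stats::setNames(list((2 / n) * (a_out - trial$target)), out_pop)
    g <- bptt_grads(net, trial$history, k = k, seed_A = seed)
    g$loss <- mean((trial$target - a_out)^2)
    return(g)
  }
  # local_dendritic: one independent pass per hidden dendritic layer
  res <- list(W = list(), loss = 0)
  hidden <- names(net$pops)[plan$types == "E" & plan$dendritic &
                              plan$layers < net$L]
  for (pop in hidden) {
    d <- trial$sens$D[[plan$idx[[pop]]]]
    n <- length(d)
    g <- bptt_grads(net, trial$history, k = k,
                    seed_D = stats::setNames(list((2 / n) * d), pop))
    yname <- find_projection(net, post = pop, direction = "Y",
                             target = "dendrite")
    if (is.null(yname)) next
    dendi <- net$projs[[yname]]$pre
    for (nm in names(net$projs))
      if (net$projs[[nm]]$post == dendi) res$W[[nm]] <- g$W[[nm]]
    res$loss <- res$loss + mean(d^2)
  }
  res
}
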