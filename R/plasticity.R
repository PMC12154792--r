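# Learning rules.  Every rule is a pure function from an immutable trial
# record (plus persistent traces) to a prescribed update; applying updates
# is a separate atomic step (apply_updates) that also enforces sign
# constraints, zero recurrent diagonals and weight bounds.

snap_vec <- function(trial, net, pop, field = "A", phase = "sensory") {
  st <- if (phase == "sensory") trial$sens else trial$sup
  st[[field]][[net$plan$idx[[pop]]]]
}

trial_dhat <- function(trial, pop) {
  d <- trial$dhat[[pop]]
  if (is.null(d))
    stop("trial record carries no nudged dendritic state for population ",
         pop, " (is this a dendritic network?)")
  d
}

#' Linear dendritic-state (LDS) weight update
#'
#' `dW[i,j] = eta * dhat_i * g_i * a_j` where `dhat` is the postsynaptic
#' nudged dendritic state, `g` the sensory-phase somatic gate and `a` the
#' sensory-phase presynaptic activity.  To the extent that the dendritic
#' state approximates the local error gradient, this update approximates
#' gradient descent.
#'
#' @param trial a trial record from [run_trial()].
#' @param net the network the trial was run on.
#' @param name projection name.
#' @return delta matrix (same shape as the projection weights).
#' @export
lds_update <- function(trial, net, name) {
  p <- net$projs[[name]]
  dhat <- trial_dhat(trial, p$post)
  g <- snap_vec(trial, net, p$post, "G")
  a_pre <- snap_vec(trial, net, p$pre)
  p$eta * outer(dhat * g, a_pre)
}

#' Dendritic-state-dependent bias update
#'
#' `dbeta_i = eta_beta * dhat_i * g_i`: the bias of each excitatory unit
#' moves linearly with its nudged dendritic state, gated by the sensory
#' somatic gate.
#'
#' @inheritParams lds_update
#' @param pop population name (must have `bias = TRUE`).
#' @return bias delta vector.
#' @export
bias_update <- function(trial, net, pop) {
  pp <- net$pops[[pop]]
  if (!isTRUE(pp$bias)) stop("population ", pop, " has no learnable bias")
  dhat <- trial_dhat(trial, pop)
  g <- snap_vec(trial, net, pop, "G")
  pp$eta_bias * dhat * g
}

#' Normalized Hebbian update
#'
#' Weight magnitudes grow in proportion to the activity correlation
#' `c[i,j] = a_i * a_j` and each postsynaptic row is then rescaled so its
#' magnitudes sum to the projection's `norm_total` (heterosynaptic
#' normalization).  The projection's `phase` selects sensory- or
#' supervised-phase activities.  Rows whose total would be zero are left
#' unchanged with a warning.
#'
#' @inheritParams lds_update
#' @return the full replacement weight matrix (already normalized).
#' @export
hebb_norm_update <- function(trial, net, name) {
  p <- net$projs[[name]]
  if (is.null(p$norm_total))
    stop("projection ", name, " is bound to the normalized Hebbian rule but has no norm_total")
  a_post <- snap_vec(trial, net, p$post, phase = p$phase)
  a_pre <- snap_vec(trial, net, p$pre, phase = p$phase)
  m <- abs(p$W) + p$eta * outer(a_post, a_pre)
  m <- pmax(m, 0)
  if (p$pre == p$post) diag(m) <- 0
  normalize_rows(m, p$norm_total, name) * p$sign
}

normalize_rows <- function(m, total, name) {
  rs <- rowSums(abs(m))
  zero <- rs <= 0
  if (any(zero)) {
    warning("projection ", name, ": ", sum(zero),
            " row(s) with zero total left unnormalized", call. = FALSE)
    rs[zero] <- total
  }
  m * (total / rs)
}

#' Dendrite-targeting inhibition update
#'
#' `dy[i,k] = -eta * d_i * a_k` with the sensory-phase dendritic state `d`
#' of the postsynaptic excitatory cell and the sensory-phase activity `a`
#' of the presynaptic dendrite-targeting interneuron.  When the dendrite is
#' depolarized (excess top-down excitation), inhibition strengthens; the
#' rule performs stochastic-gradient descent on the squared sensory
#' dendritic state, driving it toward zero.
#'
#' @inheritParams lds_update
#' @return delta matrix.
#' @export
dend_inhib_update <- function(trial, net, name) {
  p <- net$projs[[name]]
  d <- snap_vec(trial, net, p$post, "D")
  a_pre <- snap_vec(trial, net, p$pre)
  -p$eta * outer(d, a_pre)
}

#' Temporally contrastive Hebbian (TCH) update
#'
#' `dW = eta * (a~_post %o% a~_pre - a_post %o% a_pre)`: connections whose
#' activity correlation increased after the supervisory nudge are
#' strengthened, those whose correlation decreased are weakened.  To first
#' order in the nudge this recovers the dendritic error signal from somatic
#' activity alone.
#'
#' @inheritParams lds_update
#' @return delta matrix.
#' @export
tch_update <- function(trial, net, name) {
  p <- net$projs[[name]]
  a_post <- snap_vec(trial, net, p$post)
  a_pre <- snap_vec(trial, net, p$pre)
  at_post <- snap_vec(trial, net, p$post, phase = "supervised")
  at_pre <- snap_vec(trial, net, p$pre, phase = "supervised")
  p$eta * (outer(at_post, at_pre) - outer(a_post, a_pre))
}

#' BCM update with sliding threshold
#'
#' `dW[i,j] = eta * (a~_i - theta_i) * a~_i * a~_j` with supervised-phase
#' activities; potentiation above the sliding threshold, depression below.
#' After each stimulus the threshold relaxes toward `a~_i^2 / k` with time
#' constant `tau_theta`:
#' `theta <- theta + (-theta + a~^2 / k) / tau_theta`.
#'
#' @inheritParams lds_update
#' @param theta current threshold vector (defaults to the network's stored
#'   trace for the postsynaptic population).
#' @return list with `dW` (delta matrix) and `theta` (updated threshold).
#' @export
bcm_update <- function(trial, net, name, theta = NULL) {
  p <- net$projs[[name]]
  if (is.null(p$bcm_k) || p$bcm_k <= 0)
    stop("projection ", name, ": BCM scale k must be positive")
  if (is.null(theta)) theta <- net$traces$theta[[p$post]]
  at_post <- snap_vec(trial, net, p$post, phase = "supervised")
  at_pre <- snap_vec(trial, net, p$pre, phase = "supervised")
  dW <- p$eta * outer((at_post - theta) * at_post, at_pre)
  theta_new <- theta + (-theta + at_post^2 / p$bcm_k) / p$bcm_tau_theta
  list(dW = dW, theta = theta_new)
}

#' Behavioral-timescale synaptic plasticity (BTSP) update
#'
#' A saturable bidirectional rule driven by presynaptic eligibility traces
#' (ET) and postsynaptic instructive signals (IS).  For the current
#' stimulus, units with positive supervised activity set
#' `ET_j = min(a~_j, 1)` and units with positive nudged dendritic state set
#' `IS_i = 1`; the within-stimulus update for those rows is
#'
#' `dw[i,j] = eta * dhat_i * g_i * ((w_max - w) * ET_j * IS_i
#'            - w * sigma(ET_j * IS_i))`
#'
#' with [btsp_sigma()] as the saturating depression term, so weak weights
#' potentiate toward `w_max` and strong weights depress.  Traces persist
#' across stimuli: the previous stimulus's ET (decayed by `lambda`)
#' interacts with the current IS, and the previous IS (decayed to `lambda`)
#' interacts with the current ET, each producing an additional update of
#' the same form scaled by the corresponding dendritic event.  Rows whose
#' nudged dendritic state is negative fall back to the LDS rule.
#'
#' @inheritParams lds_update
#' @param traces list with `ET`, `IS`, `dg` from the previous stimulus
#'   (defaults to the network's stored traces for this projection).
#' @return list with `dW` and the updated `traces` to cache for the next
#'   stimulus.
#' @export
btsp_update <- function(trial, net, name, traces = NULL) {
  p <- net$projs[[name]]
  if (is.null(p$w_max) || p$w_max <= 0)
    stop("projection ", name, ": BTSP requires positive w_max")
  if (is.null(traces)) traces <- net$traces$btsp[[name]]
  dhat <- trial_dhat(trial, p$post)
  g <- snap_vec(trial, net, p$post, "G")
  at_pre <- snap_vec(trial, net, p$pre, phase = "supervised")
  W <- p$W

  IS_cur <- as.numeric(dhat > 0)
  ET_cur <- pmin(at_pre, 1) * (at_pre > 0)

  btsp_term <- function(rate_post, e) {
    # rate_post: eta * dhat * g per row; e: ET*IS matrix (rows post)
    rate_post * ((p$w_max - W) * e - W * btsp_sigma(e))
  }

  dW <- matrix(0, nrow(W), ncol(W))
  pos <- dhat > 0
  if (any(pos)) {
    rate <- p$eta * dhat * g * pos
    e_within <- outer(IS_cur, ET_cur)
    dW <- dW + btsp_term(rate, e_within)
    # previous stimulus's eligibility traces, decayed, with the current
    # instructive signal
    if (any(traces$ET > 0)) {
      e_cross <- outer(IS_cur, p$lambda * traces$ET)
      dW <- dW + btsp_term(rate, e_cross)
    }
  }
  # previous stimulus's instructive signal, decayed, with the current
  # eligibility traces; scaled by the previous dendritic event
  if (any(traces$IS > 0)) {
    rate_prev <- p$eta * traces$dg * traces$IS
    e_cross <- outer(p$lambda * traces$IS, ET_cur)
    dW <- dW + btsp_term(rate_prev, e_cross)
  }
  neg <- dhat < 0
  if (any(neg)) {
    a_pre_sens <- snap_vec(trial, net, p$pre)
    dW <- dW + outer(p$eta * dhat * g * neg, a_pre_sens)
  }
  list(dW = dW,
       traces = list(ET = ET_cur, IS = IS_cur, dg = dhat * g))
}

#' Learned top-down weights: TCH rule with weight normalization
#'
#' `db[j,i] = eta_B * (a~_i - a_i) * a_j` for the top-down projection onto
#' postsynaptic (lower-layer) neuron j from presynaptic (upper-layer)
#' neuron i: the presynaptic activity change across phases substitutes for
#' the upper layer's dendritic state, which is not locally available.
#' Weights are kept nonnegative and each postsynaptic row is rescaled to
#' the projection's `norm_total` (`b_sum`).
#'
#' @inheritParams lds_update
#' @return the full replacement weight matrix.
#' @export
topdown_tch_update <- function(trial, net, name) {
  p <- net$projs[[name]]
  if (p$direction != "B") stop("projection ", name, " is not top-down")
  if (is.null(p$norm_total))
    stop("projection ", name, ": the learned top-down rule requires norm_total (b_sum)")
  a_post <- snap_vec(trial, net, p$post)
  a_pre <- snap_vec(trial, net, p$pre)
  at_pre <- snap_vec(trial, net, p$pre, phase = "supervised")
  Wn <- pmax(p$W + p$eta * outer(a_post, at_pre - a_pre), 0)
  normalize_rows(Wn, p$norm_total, name)
}

#' Apply prescribed updates atomically
#'
#' All deltas for one stimulus are computed from the frozen trial record
#' and then applied together: weight deltas added (or replacement matrices
#' installed), sign constraints re-clamped (Dale's law), recurrent
#' diagonals re-zeroed, BTSP weights clamped to `[0, w_max]`, biases
#' updated, BCM thresholds and BTSP traces stored, and (for networks with
#' `symmetric_b`) top-down weights re-derived from the updated bottom-up
#' weights.
#'
#' @param net an `eiann_network`.
#' @param deltas list with optional elements `projs` (named list of
#'   `list(kind = "delta"|"replace", value = matrix)`), `biases` (named
#'   list of bias delta vectors), `theta` (named list of replacement
#'   threshold vectors), `btsp_traces` (named list of trace lists).
#' @return the updated network.
#' @export
apply_updates <- function(net, deltas) {
  for (nm in names(deltas$projs)) {
    upd <- deltas$projs[[nm]]
    p <- net$projs[[nm]]
    if (is.null(p)) stop("unknown projection in updates: ", nm)
    W <- if (identical(upd$kind, "replace")) upd$value else p$W + upd$value
    if (any(!is.finite(W)))
      stop("non-finite weight update rejected for projection ", nm)
    W <- p$sign * pmax(p$sign * W, 0)
    if (!is.null(p$w_max)) W <- p$sign * pmin(abs(W), p$w_max)
    if (p$pre == p$post) diag(W) <- 0
    net$projs[[nm]]$W <- W
  }
  for (nm in names(deltas$biases)) {
    db <- deltas$biases[[nm]]
    if (any(!is.finite(db))) stop("non-finite bias update rejected for ", nm)
    net$pops[[nm]]$bias_values <- net$pops[[nm]]$bias_values + db
  }
  for (nm in names(deltas$theta)) net$traces$theta[[nm]] <- deltas$theta[[nm]]
  for (nm in names(deltas$btsp_traces)) net$traces$btsp[[nm]] <- deltas$btsp_traces[[nm]]
  if (net$symmetric_b) net <- derive_symmetric_b(net)
  net <- refresh_plan(net)
  net
}

#' Compute all bound updates for one trial
#'
#' Dispatches every projection's learning rule and every enabled bias rule
#' on a frozen trial record, returning a deltas object for
#' [apply_updates()].  Projections bound to the backpropagation baseline
#' share a single truncated backward pass.
#'
#' @inheritParams lds_update
#' @param bptt_steps truncation window for backpropagation-bound
#'   projections.
#' @return deltas list (see [apply_updates()]).
#' @export
compute_trial_updates <- function(trial, net, bptt_steps = 3) {
  deltas <- list(projs = list(), biases = list(), theta = list(),
                 btsp_traces = list())
  rules <- vapply(net$projs, `[[`, "", "rule")
  grad_bias <- FALSE
  if (any(rules == "backprop")) {
    grads <- backprop_baseline(trial, net, mode = "global_mse",
                               k = bptt_steps)
    for (nm in names(net$projs)[rules == "backprop"])
      deltas$projs[[nm]] <- list(kind = "delta",
                                 value = -net$projs[[nm]]$eta * grads$W[[nm]])
    # gradient-trained networks also descend the loss in their biases
    grad_bias <- TRUE
    for (pop in names(net$pops)) {
      pp <- net$pops[[pop]]
      if (isTRUE(pp$bias) && pp$eta_bias > 0)
        deltas$biases[[pop]] <- -pp$eta_bias * grads$bias[[pop]]
    }
  }
  if (any(rules == "backprop_local")) {
    grads <- backprop_baseline(trial, net, mode = "local_dendritic",
                               k = bptt_steps)
    for (nm in names(net$projs)[rules == "backprop_local"])
      deltas$projs[[nm]] <- list(kind = "delta",
                                 value = -net$projs[[nm]]$eta * grads$W[[nm]])
  }
  for (nm in names(net$projs)) {
    if (net$projs[[nm]]$eta == 0) next   # rate 0 disables the rule entirely
    upd <- switch(rules[[nm]],
      fixed = NULL, backprop = NULL, backprop_local = NULL,
      lds = list(kind = "delta", value = lds_update(trial, net, nm)),
      hebb_norm = list(kind = "replace",
                       value = hebb_norm_update(trial, net, nm)),
      dend_inhib = list(kind = "delta",
                        value = dend_inhib_update(trial, net, nm)),
      tch = list(kind = "delta", value = tch_update(trial, net, nm)),
      bcm = {
        r <- bcm_update(trial, net, nm)
        deltas$theta[[net$projs[[nm]]$post]] <- r$theta
        list(kind = "delta", value = r$dW)
      },
      btsp = {
        r <- btsp_update(trial, net, nm)
        deltas$btsp_traces[[nm]] <- r$traces
        list(kind = "delta", value = r$dW)
      },
      topdown_tch = list(kind = "replace",
                         value = topdown_tch_update(trial, net, nm)),
      stop("unknown learning rule: ", rules[[nm]])
    )
    if (!is.null(upd)) deltas$projs[[nm]] <- upd
  }
  if (!grad_bias) {
    for (pop in names(net$pops)) {
      pp <- net$pops[[pop]]
      if (isTRUE(pp$bias) && pp$eta_bias > 0 && !is.null(trial$dhat[[pop]]))
        deltas$biases[[pop]] <- bias_update(trial, net, pop)
    }
  }
  deltas
}

#' Identifiers of the available learning rules
#'
#' @return character vector of rule ids accepted by [projection()].
#' @export
learning_rules <- function() {
  c("fixed", "lds", "hebb_norm", "dend_inhib", "tch", "bcm", "btsp",
    "topdown_tch", "backprop", "backprop_local")
}
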