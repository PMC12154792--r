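# Discrete-time leaky-integrator dynamics.
#
# One synchronous time step sweeps layers bottom to top.  Bottom-up drive
# uses the current step's lower-layer activities; every lateral, recurrent
# and top-down term uses the previous step's activities.  Somatic states
# integrate with time constant tau:
#     s[t] = s[t-1] + ( -s[t-1] + total drive ) / tau
# Dendritic states of hidden excitatory cells are recomputed each step from
# the previous step's top-down excitation and dendrite-targeting inhibition;
# during the supervised phase they are replaced by the frozen nudged states.
# Activities are a = relu(s + beta) + d * gate(s + beta) where a dendrite
# exists, and a = relu(s + beta) otherwise.

zero_state <- function(net) {
  sizes <- net$plan$sizes
  S <- lapply(sizes, numeric)
  list(S = S, A = S, D = S, G = S)
}

#' Advance the network dynamics by one time step
#'
#' @param net an `eiann_network`.
#' @param state state list from the previous step (see [zero_state] inside
#'   the package); use [equilibrate()] for whole phases.
#' @param input_vector numeric input activity vector.
#' @param dhat optional named list of frozen nudged dendritic states (one
#'   entry per dendritic E population, plus the output population); when
#'   supplied the step runs in the supervised phase.
#' @param weights optional list of weight matrices overriding the network's
#'   (used internally to avoid repeated extraction).
#' @return the updated state: lists `S`, `A`, `D`, `G` indexed by
#'   population.
#' @export
step_dynamics <- function(net, state, input_vector, dhat = NULL,
                          weights = NULL) {
  plan <- net$plan
  if (length(input_vector) != plan$sizes[[plan$input]])
    stop("input vector has length ", length(input_vector),
         " but the Input population has ", plan$sizes[[plan$input]], " units")
  if (is.null(weights)) weights <- lapply(net$projs, `[[`, "W")
  tau <- net$cfg$tau
  L <- net$L
  supervised <- !is.null(dhat)
  if (supervised) {
    dh <- rep(list(NULL), length(plan$sizes))
    for (nm in names(dhat)) dh[[plan$idx[[nm]]]] <- dhat[[nm]]
  }

  Sp <- state$S; Ap <- state$A
  S <- Sp; A <- Ap; D <- state$D; G <- state$G
  A[[plan$input]] <- input_vector

  for (pi_ in plan$update_order) {
    # dendritic state (hidden dendritic E cells; output dendrite is clamped
    # to zero during the sensory phase and to the frozen nudge afterwards)
    has_dend <- plan$dendritic[[pi_]]
    if (has_dend) {
      if (supervised && !is.null(dh[[pi_]])) {
        d <- dh[[pi_]]
      } else if (plan$layers[[pi_]] == L || net$cfg$exact_cancellation ||
                 supervised) {
        d <- numeric(plan$sizes[[pi_]])
      } else {
        d <- numeric(plan$sizes[[pi_]])
        for (j in plan$dend_prev[[pi_]])
          d <- d + as.vector(weights[[j]] %*% Ap[[plan$proj_pre[j]]])
      }
      D[[pi_]] <- d
    }
    drive <- numeric(plan$sizes[[pi_]])
    for (j in plan$soma_cur[[pi_]])
      drive <- drive + as.vector(weights[[j]] %*% A[[plan$proj_pre[j]]])
    for (j in plan$soma_prev[[pi_]])
      drive <- drive + as.vector(weights[[j]] %*% Ap[[plan$proj_pre[j]]])
    s <- Sp[[pi_]] + (drive - Sp[[pi_]]) / tau
    S[[pi_]] <- s
    z <- s + plan$bias[[pi_]]
    g <- as.numeric(z > 0)
    G[[pi_]] <- g
    a <- pmax(z, 0)
    if (has_dend) {
      a <- a + D[[pi_]] * g
      if (net$cfg$clamp_activity_nonneg) a <- pmax(a, 0)
    }
    A[[pi_]] <- a
  }
  bad <- vapply(S, function(s) any(!is.finite(s)) ||
                  max(abs(s), 0) > net$cfg$divergence_bound, TRUE)
  if (any(bad))
    stop("dynamics instability: somatic state non-finite or beyond ",
         net$cfg$divergence_bound, " in population(s) ",
         paste(names(net$pops)[bad], collapse = ", "),
         "; reduce projection w_init scales or learning rates")
  list(S = S, A = A, D = D, G = G)
}

#' Equilibrate the network under a constant input
#'
#' Applies [step_dynamics()] `steps` times while the input is held constant,
#' starting from `state` (all-zero by default).  The oscillation residual is
#' the mean over all non-input units of the absolute change of activity in
#' the final step; a well-configured network settles to a fixed point and
#' the residual decays geometrically.
#'
#' @inheritParams step_dynamics
#' @param steps number of time steps (default: the network's
#'   `steps_per_phase`).
#' @param state starting state; defaults to rest (all zeros).
#' @param retain_history if `TRUE`, keep the state after every step (needed
#'   by the truncated backpropagation-through-time baseline).
#' @return list with `state` (final), `residual` (oscillation residual) and
#'   `history` (list of states from step 0, or `NULL`).
#' @export
equilibrate <- function(net, input_vector, steps = net$cfg$steps_per_phase,
                        state = NULL, dhat = NULL, retain_history = FALSE,
                        weights = NULL) {
  stopifnot(steps >= 1)
  if (is.null(state)) state <- zero_state(net)
  if (is.null(weights)) weights <- lapply(net$projs, `[[`, "W")
  history <- if (retain_history) vector("list", steps + 1L) else NULL
  if (retain_history) history[[1L]] <- state
  prev_A <- state$A
  for (t in seq_len(steps)) {
    if (t == steps) prev_A <- state$A
    state <- step_dynamics(net, state, input_vector, dhat = dhat,
                           weights = weights)
    if (retain_history) history[[t + 1L]] <- state
  }
  non_input <- net$plan$update_order
  num <- 0; den <- 0
  for (pi_ in non_input) {
    num <- num + sum(abs(state$A[[pi_]] - prev_A[[pi_]]))
    den <- den + length(state$A[[pi_]])
  }
  list(state = state, residual = num / den, history = history)
}
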