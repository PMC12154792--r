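#' Describe one neuronal population
#'
#' A population is a homogeneous group of units of a single cell type within
#' one layer.  Excitatory ("E") cells may carry a separate apical-dendrite
#' compartment (`dendrite = TRUE`) and learnable bias parameters; interneuron
#' populations target either the soma ("SomaI") or the dendrite ("DendI") of
#' the excitatory cells in their layer.
#'
#' @param name unique population name, e.g. `"E1"`.
#' @param layer integer layer index; the input population is layer 0 and the
#'   output layer is the largest index present.
#' @param type one of `"Input"`, `"E"`, `"SomaI"`, `"DendI"`.
#' @param size positive integer number of units.
#' @param dendrite logical; `TRUE` only for E cells in dendritic networks.
#' @param bias logical; enable learnable per-unit biases (E cells only).
#' @param eta_bias nonnegative bias learning rate.
#' @return a `population` spec (a list).
#' @export
population <- function(name, layer, type, size,
                       dendrite = FALSE, bias = FALSE, eta_bias = 0) {
  type <- match.arg(type, c("Input", "E", "SomaI", "DendI"))
  if (size < 1) stop("population '", name, "': size must be >= 1")
  if (bias && type != "E") stop("population '", name, "': biases are restricted to E cells")
  if (dendrite && type != "E") stop("population '", name, "': only E cells have dendrites")
  structure(list(name = name, layer = as.integer(layer), type = type,
                 size = as.integer(size), dendrite = isTRUE(dendrite),
                 bias = isTRUE(bias), eta_bias = eta_bias,
                 bias_values = numeric(size)),
            class = "eiann_population")
}

#' Describe one synaptic projection
#'
#' A projection is a full weight matrix from a presynaptic population to a
#' compartment (soma or dendrite) of a postsynaptic population.  Its sign is
#' fixed by the presynaptic cell type (Dale's law): +1 for excitatory
#' presynaptic populations, -1 for inhibitory ones.  Weight magnitudes are
#' initialized i.i.d. uniform on `[0, w_init / n_pre]`.
#'
#' The `direction` tag records the circuit role and determines the time
#' index used during the dynamics: bottom-up (`"W"`) projections read the
#' presynaptic activity of the current time step (layers are swept bottom to
#' top within a step), while lateral (`"Y"`, `"Q"`), recurrent (`"R"`) and
#' top-down (`"B"`) projections read the previous step.
#'
#' @param pre,post names of the pre- and postsynaptic populations.
#' @param direction one of `"W"` (bottom-up), `"Y"` (lateral inhibition),
#'   `"Q"` (lateral excitation onto interneurons), `"R"` (recurrent
#'   inhibition between interneurons), `"B"` (top-down excitation).
#' @param target `"soma"` or `"dendrite"`; only E-cell dendrites receive
#'   dendrite-targeted projections (top-down B and lateral DendI inhibition).
#' @param sign +1 or -1; must match the presynaptic cell type.
#' @param rule learning-rule identifier (see [learning_rules()]) or
#'   `"fixed"`.
#' @param eta nonnegative learning rate.
#' @param w_init positive initialization scale.
#' @param norm_total total per-row weight magnitude maintained by the
#'   normalized rules (`w_sum` for Hebbian, `b_sum` for the top-down rule),
#'   or `NULL`.
#' @param w_max maximum weight (BTSP rule only).
#' @param lambda cross-stimulus trace decay in `[0, 1]` (BTSP rule only).
#' @param phase which trial phase supplies the activities for correlation
#'   rules: `"sensory"` (default) or `"supervised"`.
#' @param bcm_k,bcm_tau_theta BCM rule constants: threshold scale and
#'   sliding-threshold time constant (in stimuli).
#' @return a `projection` spec (a list; weights are attached by
#'   [build_network()]).
#' @export
projection <- function(pre, post, direction, target = "soma", sign = 1,
                       rule = "fixed", eta = 0, w_init = 1,
                       norm_total = NULL, w_max = NULL, lambda = 0,
                       phase = "sensory", bcm_k = NULL, bcm_tau_theta = NULL) {
  direction <- match.arg(direction, c("W", "Y", "Q", "R", "B"))
  target <- match.arg(target, c("soma", "dendrite"))
  phase <- match.arg(phase, c("sensory", "supervised"))
  if (!sign %in% c(-1, 1)) stop("projection sign must be +1 or -1")
  if (w_init <= 0) stop("projection ", pre, "->", post, ": w_init must be positive")
  if (!is.null(w_max) && w_max <= 0) stop("projection ", pre, "->", post, ": w_max must be positive")
  if (lambda < 0 || lambda > 1) stop("projection ", pre, "->", post, ": lambda must lie in [0, 1]")
  structure(list(pre = pre, post = post, direction = direction,
                 target = target, sign = sign, rule = rule, eta = eta,
                 w_init = w_init, norm_total = norm_total, w_max = w_max,
                 lambda = lambda, phase = phase, bcm_k = bcm_k,
                 bcm_tau_theta = bcm_tau_theta, W = NULL),
            class = "eiann_projection")
}

# Deterministic per-projection random substream: adding or removing one
# projection must not perturb the initialization of the others.
proj_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147480009
  as.integer((h + (seed %% 65536) * 32749 + seed) %% .Machine$integer.max)
}

#' Initialize the weights of one projection
#'
#' Magnitudes are drawn i.i.d. uniform on `[0, w_init / n_pre]` where
#' `n_pre` is the presynaptic population size, then multiplied by the
#' projection sign.  Self-connections of recurrent projections are set to
#' zero.  Deterministic for a given seed, with one named substream per
#' projection.
#'
#' @param proj a [projection()] spec with `pre`/`post` sizes attached, or
#'   taken from a built network.
#' @param n_pre,n_post population sizes.
#' @param seed integer seed.
#' @param name substream name (defaults to `"pre->post"`).
#' @return a `n_post x n_pre` weight matrix.
#' @export
init_weights <- function(proj, n_pre, n_post, seed,
                         name = paste0(proj$pre, "->", proj$post)) {
  if (proj$w_init <= 0) stop("w_init must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(proj_seed(seed, name))
  W <- matrix(stats::runif(n_post * n_pre, 0, proj$w_init / n_pre),
              nrow = n_post, ncol = n_pre)
  W <- W * proj$sign
  if (proj$pre == proj$post) diag(W) <- 0
  W
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Assemble and initialize a network
#'
#' Validates an architecture (a list of [population()] and [projection()]
#' specs plus dynamics configuration), initializes all weights from seeded
#' uniform distributions, and precomputes the update plan used by the
#' dynamics.
#'
#' @param populations list of [population()] specs (exactly one Input
#'   population, in layer 0).
#' @param projections list of [projection()] specs.
#' @param tau integration time constant of the leaky somatic dynamics.
#' @param steps_per_phase number of time steps per equilibration phase.
#' @param dendrite_clip bound applied to nudged dendritic states.
#' @param seed integer seed for weight initialization.
#' @param symmetric_b if `TRUE`, every top-down B projection is slaved to
#'   the transpose of the corresponding bottom-up E-to-E weights,
#'   `B(l) = b_scale * t(W(l+1))`, re-derived after every weight update.
#' @param b_scale scale factor for symmetric top-down weights.
#' @param exact_cancellation if `TRUE`, sensory-phase dendritic states are
#'   held at zero and nudge propagation subtracts the sensory top-down
#'   drive, emulating perfect cancellation by dendritic inhibition (used by
#'   analysis fixtures; biological networks learn the cancellation instead).
#' @param clamp_activity_nonneg if `TRUE`, nudged and re-equilibrated
#'   activities are clipped at zero from below; default `FALSE` applies the
#'   nudge equation literally, so a strongly negative dendritic state can
#'   produce a negative activity.
#' @param nudge_scale scale applied to the output nudge `T - A`; 1
#'   reproduces the full supervisory signal, smaller values probe the
#'   small-nudge (gradient) limit.
#' @param divergence_bound somatic states exceeding this magnitude abort the
#'   dynamics with an instability error.
#' @return an object of class `eiann_network`.
#' @export
build_network <- function(populations, projections, tau = 3,
                          steps_per_phase = 15, dendrite_clip = 1,
                          seed = 1, symmetric_b = FALSE, b_scale = 1,
                          exact_cancellation = FALSE,
                          clamp_activity_nonneg = FALSE,
                          nudge_scale = 1,
                          divergence_bound = 1e6) {
  stopifnot(tau > 0, steps_per_phase >= 1, dendrite_clip > 0)
  pops <- stats::setNames(populations, vapply(populations, `[[`, "", "name"))
  if (anyDuplicated(names(pops))) stop("duplicate population names")
  layers <- vapply(pops, `[[`, 0L, "layer")
  types <- vapply(pops, `[[`, "", "type")
  if (sum(types == "Input") != 1) stop("exactly one Input population is required")
  if (layers[types == "Input"] != 0) stop("the Input population must be in layer 0")
  L <- max(layers)
  if (any(types == "DendI" & layers == L))
    stop("DendI populations exist only in hidden layers")

  names(projections) <- vapply(projections, function(p) paste0(p$pre, "->", p$post), "")
  if (anyDuplicated(names(projections))) stop("duplicate projections")

  for (p in projections) {
    if (!p$pre %in% names(pops)) stop("unknown presynaptic population: ", p$pre)
    if (!p$post %in% names(pops)) stop("unknown postsynaptic population: ", p$post)
    pre <- pops[[p$pre]]; post <- pops[[p$post]]
    if (post$type == "Input") stop("Input populations receive no projections")
    expected_sign <- if (pre$type %in% c("Input", "E")) 1 else -1
    if (p$sign != expected_sign)
      stop("projection ", p$pre, "->", p$post, " violates Dale's law: sign must be ", expected_sign)
    if (p$target == "dendrite" && !(post$type == "E" && post$dendrite))
      stop("projection ", p$pre, "->", p$post,
           ": only E-cell dendrite compartments receive dendrite-targeted projections")
  }

  net <- structure(list(
    pops = pops, projs = projections, L = L,
    cfg = list(tau = tau, steps_per_phase = steps_per_phase,
               dendrite_clip = dendrite_clip,
               exact_cancellation = isTRUE(exact_cancellation),
               clamp_activity_nonneg = isTRUE(clamp_activity_nonneg),
               nudge_scale = nudge_scale,
               divergence_bound = divergence_bound),
    symmetric_b = isTRUE(symmetric_b), b_scale = b_scale,
    seed = as.integer(seed),
    traces = list(btsp = list(), theta = list())
  ), class = "eiann_network")

  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    net$projs[[nm]]$W <- init_weights(p, net$pops[[p$pre]]$size,
                                      net$pops[[p$post]]$size, seed, nm)
  }
  net <- init_traces(net)
  if (net$symmetric_b) net <- derive_symmetric_b(net)
  net$plan <- build_plan(net)
  net
}

# Tie each top-down B projection to the transpose of the bottom-up E->E
# weights of the layer above.
derive_symmetric_b <- function(net) {
  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    if (p$direction != "B") next
    up <- find_projection(net, pre = p$post, post = p$pre, direction = "W")
    if (is.null(up))
      stop("symmetric_b: no bottom-up projection matching top-down ", nm)
    net$projs[[nm]]$W <- net$b_scale * t(net$projs[[up]]$W)
  }
  net
}

find_projection <- function(net, pre = NULL, post = NULL, direction = NULL,
                            target = NULL) {
  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    if (!is.null(pre) && p$pre != pre) next
    if (!is.null(post) && p$post != post) next
    if (!is.null(direction) && p$direction != direction) next
    if (!is.null(target) && p$target != target) next
    return(nm)
  }
  NULL
}

init_traces <- function(net) {
  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    if (identical(p$rule, "btsp")) {
      if (is.null(p$w_max)) stop("BTSP projection ", nm, " requires w_max")
      net$traces$btsp[[nm]] <- list(
        ET = numeric(net$pops[[p$pre]]$size),
        IS = numeric(net$pops[[p$post]]$size),
        dg = numeric(net$pops[[p$post]]$size))
    }
    if (identical(p$rule, "bcm")) {
      post <- p$post
      if (is.null(net$traces$theta[[post]]))
        net$traces$theta[[post]] <- numeric(net$pops[[post]]$size)
    }
  }
  net
}

# Precompute integer-indexed update order and per-population incoming
# projection lists, split by compartment and time index.
build_plan <- function(net) {
  pop_names <- names(net$pops)
  idx <- stats::setNames(seq_along(pop_names), pop_names)
  layers <- vapply(net$pops, `[[`, 0L, "layer")
  types <- vapply(net$pops, `[[`, "", "type")
  type_rank <- c(Input = 0L, E = 1L, SomaI = 2L, DendI = 3L)
  ord <- order(layers, type_rank[types])
  update_order <- ord[types[ord] != "Input"]

  soma_cur <- soma_prev <- dend_prev <- rep(list(integer(0)), length(pop_names))
  proj_pre <- proj_post <- integer(length(net$projs))
  for (j in seq_along(net$projs)) {
    p <- net$projs[[j]]
    proj_pre[j] <- idx[[p$pre]]
    proj_post[j] <- idx[[p$post]]
    pi_ <- idx[[p$post]]
    if (p$target == "dendrite") {
      dend_prev[[pi_]] <- c(dend_prev[[pi_]], j)
    } else if (p$direction == "W") {
      soma_cur[[pi_]] <- c(soma_cur[[pi_]], j)
    } else {
      soma_prev[[pi_]] <- c(soma_prev[[pi_]], j)
    }
  }
  list(idx = idx, update_order = update_order, layers = layers,
       types = types, soma_cur = soma_cur, soma_prev = soma_prev,
       dend_prev = dend_prev, proj_pre = proj_pre, proj_post = proj_post,
       input = unname(idx[types == "Input"]),
       sizes = vapply(net$pops, `[[`, 0L, "size"),
       dendritic = vapply(net$pops, function(p) isTRUE(p$dendrite), TRUE),
       bias = lapply(net$pops, `[[`, "bias_values"))
}

# Refresh plan caches that depend on mutable parameters (biases).
refresh_plan <- function(net) {
  net$plan$bias <- lapply(net$pops, `[[`, "bias_values")
  net
}

#' @export
print.eiann_network <- function(x, ...) {
  cat("<eiann_network> ", x$L, "-layer network, ",
      length(x$pops), " populations, ", length(x$projs), " projections\n", sep = "")
  for (p in x$pops)
    cat(sprintf("  pop %-8s layer %d  %-6s n=%-4d%s%s\n", p$name, p$layer,
                p$type, p$size, if (p$dendrite) " +dendrite" else "",
                if (p$bias) " +bias" else ""))
  for (nm in names(x$projs)) {
    p <- x$projs[[nm]]
    cat(sprintf("  proj %-18s %s %-9s sign %+d  rule %s\n", nm, p$direction,
                p$target, p$sign, p$rule))
  }
  invisible(x)
}

#' Weight matrix accessor
#'
#' @param net an `eiann_network`.
#' @param name projection name `"pre->post"`.
#' @return the weight matrix.
#' @export
get_weights <- function(net, name) {
  if (is.null(net$projs[[name]])) stop("unknown projection: ", name)
  net$projs[[name]]$W
}
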