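#' Center excitatory thresholds at the network's operating point
#'
#' Biological neurons sit near their firing threshold at rest.  This
#' initializer equilibrates the network once on a reference stimulus
#' (typically the dataset mean) and sets each excitatory unit's bias to
#' `-factor` times its equilibrium somatic state, so that unit thresholds
#' straddle the operating point instead of leaving every rectifier
#' permanently open.  With all-positive inputs and sign-constrained
#' weights this is what makes the rectifier nonlinearity effective from
#' the start of training.
#'
#' @param net a built `eiann_network` whose biases are still zero.
#' @param x_ref reference stimulus (e.g. column means of the training
#'   inputs).
#' @param factor fraction of the equilibrium somatic state to subtract;
#'   1 puts the threshold exactly at the operating point, smaller values
#'   keep more units active.
#' @param pops populations to center (default: all E populations with
#'   biases enabled).
#' @return the network with centered biases.
#' @export
center_biases <- function(net, x_ref, factor = 0.9, pops = NULL) {
  plan <- net$plan
  if (is.null(pops))
    pops <- names(net$pops)[vapply(net$pops, function(p)
      isTRUE(p$bias), TRUE)]
  # center layer by layer so that upper layers see the already-centered
  # activities of the layers below
  ord <- pops[order(plan$layers[pops])]
  for (pop in ord) {
    eq <- equilibrate(net, x_ref)
    net$pops[[pop]]$bias_values <- -factor * eq$state$S[[plan$idx[[pop]]]]
    net <- refresh_plan(net)
  }
  net
}

# Reference architectures for the 2D spirals task (2 input units; hidden
# layer 1: 128 E / 32 SomaI / 54 DendI; hidden layer 2: 32 E / 8 SomaI /
# 13 DendI; output: 4 E / 4 SomaI).  Hyperparameter defaults were chosen by
# a coarse search on the spirals fixture (see the package vignette) and are
# deliberately conservative: somatic inhibition is weak enough that the
# sensory dynamics settle within 15 steps.

#' Build a spirals-task network
#'
#' @param variant one of:
#'   \describe{
#'     \item{dendritic_lds}{full dendritic architecture, bottom-up weights
#'       learned with the LDS rule, symmetric top-down weights, learned
#'       dendritic inhibition (normalized Hebbian onto DendI, dendritic
#'       inhibition rule onto E dendrites), learnable biases.}
#'     \item{dendritic_lds_nobias}{same but with bias learning disabled.}
#'     \item{dendritic_btsp}{bottom-up weights learned with BTSP.}
#'     \item{dendritic_lds_learned_b}{independent top-down weights learned
#'       with the normalized temporally contrastive rule.}
#'     \item{dendritic_lds_fixed_b}{independent top-down weights frozen at
#'       their random initialization (feedback alignment control).}
#'     \item{backprop}{same excitatory-inhibitory skeleton without
#'       dendrites, bottom-up weights trained by truncated
#'       backpropagation.}
#'   }
#' @param seed integer seed for weight initialization.
#' @param eta_w bottom-up learning rate (scalar, or one value per layer).
#' @param eta_bias bias learning rate.
#' @param eta_y dendritic-inhibition learning rate.
#' @param eta_hebb,hebb_w_sum normalized-Hebbian rate and row total for
#'   DendI inputs.
#' @param b_scale top-down scale (symmetric variants) .
#' @param b_sum,eta_b row total and rate for learned top-down weights.
#' @param w_init_w,w_init_lat bottom-up (scalar or per layer) and lateral
#'   initialization scales.
#' @param w_init_v,w_init_y initialization scales for the bottom-up drive
#'   onto SomaI cells and for the SomaI-to-E inhibition (scalar or per
#'   layer); default to `w_init_lat`.
#' @param w_max,lambda BTSP bound and trace decay.
#' @param ... passed to [build_network()].
#' @return an `eiann_network`.
#' @export
spirals_network <- function(variant = c("dendritic_lds",
                                        "dendritic_lds_nobias",
                                        "dendritic_btsp",
                                        "dendritic_lds_learned_b",
                                        "dendritic_lds_fixed_b",
                                        "backprop"),
                            seed = 1,
                            eta_w = c(0.032, 0.016, 0.048), eta_bias = 0.038,
                            eta_y = 0.077, eta_hebb = 0.012, hebb_w_sum = 3.2,
                            b_scale = 0.52, b_sum = 0.25, eta_b = 0.02,
                            w_init_w = c(4, 2.2, 1.1), w_init_lat = 0.37,
                            w_init_v = c(0.37, 0.37, 2),
                            w_init_y = c(0.37, 0.37, 1),
                            w_max = 1.5, lambda = 0.4, ...) {
  variant <- match.arg(variant)
  dendritic <- variant != "backprop"
  bias <- variant != "dendritic_lds_nobias"
  w_rule <- switch(variant, dendritic_btsp = "btsp", backprop = "backprop",
                   "lds")
  sizes <- list(E = c(128, 32, 4), SomaI = c(32, 8, 4), DendI = c(54, 13))

  pops <- list(population("Input", 0, "Input", 2))
  for (l in 1:3) {
    pops <- c(pops, list(
      population(paste0("E", l), l, "E", sizes$E[l], dendrite = dendritic,
                 bias = bias, eta_bias = if (bias) eta_bias else 0),
      population(paste0("SomaI", l), l, "SomaI", sizes$SomaI[l])))
    if (dendritic && l < 3)
      pops <- c(pops, list(population(paste0("DendI", l), l, "DendI",
                                      sizes$DendI[l])))
  }

  eta_w <- rep_len(eta_w, 3)
  w_init_w <- rep_len(w_init_w, 3)
  w_init_v <- rep_len(w_init_v, 3)
  w_init_y <- rep_len(w_init_y, 3)
  bu <- function(pre, post, rule, eta, w0) {
    extra <- if (rule == "btsp") list(w_max = w_max, lambda = lambda) else list()
    do.call(projection, c(list(pre, post, "W", w_init = w0,
                               rule = rule, eta = eta), extra))
  }
  projs <- list()
  pre_e <- "Input"
  for (l in 1:3) {
    E <- paste0("E", l); SI <- paste0("SomaI", l)
    projs <- c(projs, list(
      bu(pre_e, E, w_rule, eta_w[l], w_init_w[l]),
      projection(pre_e, SI, "W", w_init = w_init_v[l]),
      projection(SI, E, "Y", sign = -1, w_init = w_init_y[l]),
      projection(E, SI, "Q", w_init = w_init_lat),
      projection(SI, SI, "R", sign = -1, w_init = w_init_lat / 2)))
    if (dendritic && l < 3) {
      DI <- paste0("DendI", l)
      projs <- c(projs, list(
        projection(E, DI, "Q", w_init = 0.5, rule = "hebb_norm",
                   eta = eta_hebb, norm_total = hebb_w_sum),
        projection(DI, DI, "R", sign = -1, w_init = w_init_lat / 2),
        projection(DI, E, "Y", sign = -1, target = "dendrite",
                   w_init = 0.1, rule = "dend_inhib", eta = eta_y),
        projection(paste0("E", l + 1), E, "B", target = "dendrite",
                   w_init = b_sum,
                   rule = if (variant == "dendritic_lds_learned_b")
                     "topdown_tch" else "fixed",
                   eta = eta_b,
                   norm_total = if (variant == "dendritic_lds_learned_b")
                     b_sum else NULL)))
    }
    pre_e <- E
  }
  symmetric <- dendritic && !variant %in% c("dendritic_lds_learned_b",
                                            "dendritic_lds_fixed_b")
  build_network(pops, projs, seed = seed, symmetric_b = symmetric,
                b_scale = b_scale, ...)
}
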