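#' Rectified linear activation and its gate
#'
#' `relu()` returns `max(0, z)` elementwise.  `relu_gate()` returns the
#' derivative used to gate dendritic input and plasticity: 1 where `z > 0`
#' and 0 otherwise (strictly greater, so the gate is closed at exactly zero).
#'
#' @param z numeric vector of somatic states.
#' @return numeric vector of the same length.
#' @examples
#' relu(c(-1, 0, 2.5))      # 0 0 2.5
#' relu_gate(c(-1, 0, 2.5)) # 0 0 1
#' @export
relu <- function(z) {
  pmax(z, 0)
}

#' @rdname relu
#' @export
relu_gate <- function(z) {
  as.numeric(z > 0)
}

#' Saturating sigmoid used by the BTSP learning rule
#'
#' A logistic function with midpoint 0.01 and slope 1/0.005, rescaled and
#' offset so that it meets the edge constraints exactly:
#' `btsp_sigma(0) == 0` and `btsp_sigma(1) == 1`.  It rises steeply near
#' zero, so even a small product of eligibility trace and instructive
#' signal recruits nearly full synaptic depression.
#'
#' @param z numeric vector, typically a product of an eligibility trace and
#'   an instructive signal, in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
btsp_sigma <- function(z) {
  sig_hat <- function(u) 1 / (1 + exp(-(u - 0.01) / 0.005))
  s0 <- sig_hat(0)
  s1 <- sig_hat(1)
  (sig_hat(z) - s0) / (s1 - s0)
}
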