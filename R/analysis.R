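# Measurement suite: stimulus selectivity, Moran's I spatial
# autocorrelation, gradient receptive fields, weight-update alignment
# angles, and classification accuracy.

#' Stimulus selectivity index
#'
#' `S = (1 - (sum(a)/n)^2 / (sum(a^2)/n)) / (1 - 1/n)` for a vector of
#' nonnegative responses to `n` stimuli: 0 for uniform responses, 1 for a
#' unit that responds to a single stimulus only.  Invariant to positive
#' rescaling of the responses.  An all-zero response vector has no defined
#' selectivity and returns `NA`.
#'
#' @param responses nonnegative response vector (length >= 2).
#' @return selectivity in `[0, 1]`, or `NA` for an all-zero vector.
#' @export
selectivity <- function(responses) {
  n <- length(responses)
  if (n < 2) stop("selectivity requires responses to at least 2 stimuli")
  if (any(responses < 0)) stop("selectivity expects nonnegative responses")
  ss <- sum(responses^2)
  if (ss == 0) return(NA_real_)
  (1 - (sum(responses) / n)^2 / (ss / n)) / (1 - 1 / n)
}

#' Moran's I spatial autocorrelation of an image
#'
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with binary rook (4-neighbour) weights: 1 for vertically or horizontally
#' adjacent pixels, 0 otherwise, and `W` the sum of all weights.  Values
#' near 0 for spatially unstructured images, approaching 1 for smooth
#' spatial domains, negative for checkerboard-like anticorrelation.
#' Constant images have zero variance and return `NA`.
#'
#' @param image numeric matrix (at least 2 pixels in one dimension).
#' @return Moran's I, or `NA` for a constant image.
#' @export
morans_i <- function(image) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (length(image) < 2) stop("Moran's I is undefined for a single pixel")
  xc <- image - mean(image)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  nr <- nrow(image); nc <- ncol(image)
  # horizontal and vertical neighbour products, each pair counted twice in
  # the double sum (w_ij = w_ji = 1)
  cross <- 0
  if (nr > 1) cross <- cross + sum(xc[-1, , drop = FALSE] * xc[-nr, , drop = FALSE])
  if (nc > 1) cross <- cross + sum(xc[, -1, drop = FALSE] * xc[, -nc, drop = FALSE])
  n_pairs <- (nr - 1) * nc + nr * (nc - 1)
  N <- nr * nc
  W <- 2 * n_pairs
  (N / W) * (2 * cross) / denom
}

#' Alignment angle between two update matrices
#'
#' The arccosine of the cosine similarity of the flattened matrices, in
#' degrees: 0 for identical directions, 90 for orthogonal updates, 180 for
#' antiparallel ones.  Used both to compare a rule's weight updates to the
#' gradient and to compare top-down weights `B` to the transpose of the
#' bottom-up weights.
#'
#' @param U,V numeric matrices (or vectors) of identical shape.
#' @return angle in degrees, or `NA` if either input has zero norm.
#' @export
alignment_angle <- function(U, V) {
  u <- as.numeric(U); v <- as.numeric(V)
  if (length(u) != length(v)) stop("U and V must have the same shape")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cs <- sum(u * v) / (nu * nv)
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Gradient receptive field of a unit
#'
#' For each image, the gradient of the unit's equilibrated activity with
#' respect to every input feature is computed through the recurrent
#' dynamics (same truncation window as the backpropagation baseline), with
#' sign such that positive values mark excitatory influence.  Maps are
#' averaged over images and normalized to unit maximum magnitude.
#'
#' @param net a built network with frozen weights.
#' @param pop population name of the unit.
#' @param unit unit index within the population.
#' @param images matrix of input vectors (one row per image).
#' @param k truncation window for the backward pass.
#' @param normalize divide by the maximum absolute value (if nonzero).
#' @return numeric vector over input features (the receptive-field map).
#' @export
receptive_field <- function(net, pop, unit, images, k = 3,
                            normalize = TRUE) {
  if (is.null(net$pops[[pop]])) stop("unknown population: ", pop)
  if (unit < 1 || unit > net$pops[[pop]]$size)
    stop("unit index out of range for population ", pop)
  if (!is.matrix(images)) images <- matrix(images, nrow = 1)
  if (nrow(images) < 1) stop("image set is empty")
  acc <- numeric(ncol(images))
  seed_vec <- numeric(net$pops[[pop]]$size)
  seed_vec[unit] <- 1
  for (i in seq_len(nrow(images))) {
    eq <- equilibrate(net, images[i, ], retain_history = TRUE)
    g <- bptt_grads(net, eq$history, k = k,
                    seed_A = stats::setNames(list(seed_vec), pop))
    acc <- acc + g$input
  }
  map <- acc / nrow(images)
  if (normalize && max(abs(map)) > 0) map <- map / max(abs(map))
  map
}

#' Classification accuracy of the sensory response
#'
#' Each sample is presented for one sensory-phase equilibration (no nudge);
#' the predicted class is the most active output excitatory unit (ties
#' resolved toward the lowest index).
#'
#' @param net a built network.
#' @param dataset a `labelled_dataset`.
#' @return accuracy in percent.
#' @export
evaluate_accuracy <- function(net, dataset) {
  plan <- net$plan
  out_pop <- names(net$pops)[plan$types == "E" & plan$layers == net$L]
  oi <- plan$idx[[out_pop]]
  weights <- lapply(net$projs, `[[`, "W")
  n <- nrow(dataset$inputs)
  correct <- 0L
  for (i in seq_len(n)) {
    eq <- equilibrate(net, dataset$inputs[i, ], weights = weights)
    if (which.max(eq$state$A[[oi]]) == dataset$labels[i])
      correct <- correct + 1L
  }
  100 * correct / n
}

#' Per-unit response metrics over a dataset
#'
#' Equilibrates the network on every sample and returns, per unit of the
#' requested populations, the class-averaged responses and the selectivity
#' index over classes.
#'
#' @param net a built network.
#' @param dataset a `labelled_dataset`.
#' @param pops population names (default: all E and DendI populations
#'   outside the input layer).
#' @return data frame with columns `pop`, `unit`, `selectivity`, and mean
#'   activity per class.
#' @export
population_selectivity <- function(net, dataset, pops = NULL) {
  plan <- net$plan
  if (is.null(pops))
    pops <- names(net$pops)[plan$types %in% c("E", "DendI")]
  weights <- lapply(net$projs, `[[`, "W")
  n_classes <- ncol(dataset$one_hot)
  sums <- lapply(pops, function(p) matrix(0, net$pops[[p]]$size, n_classes))
  names(sums) <- pops
  counts <- numeric(n_classes)
  for (i in seq_len(nrow(dataset$inputs))) {
    eq <- equilibrate(net, dataset$inputs[i, ], weights = weights)
    cl <- dataset$labels[i]
    counts[cl] <- counts[cl] + 1
    for (p in pops)
      sums[[p]][, cl] <- sums[[p]][, cl] + eq$state$A[[plan$idx[[p]]]]
  }
  out <- do.call(rbind, lapply(pops, function(p) {
    m <- sweep(sums[[p]], 2, pmax(counts, 1), "/")
    data.frame(pop = p, unit = seq_len(nrow(m)),
               selectivity = apply(pmax(m, 0), 1, selectivity))
  }))
  rownames(out) <- NULL
  out
}
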