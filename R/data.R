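# Task inputs: a seeded 2D spirals generator (the nonlinear classification
# benchmark used throughout), an MNIST IDX reader for optional full-scale
# runs, and small deterministic fixture networks for oracle tests.

#' Generate a seeded multi-class 2D spirals dataset
#'
#' Class `c` occupies the arm
#' `(r * cos(phi + 2*pi*c/n_classes), r * sin(phi + 2*pi*c/n_classes))`
#' with radius proportional to angle, `phi` spanning `turns` full rotations.
#' Points are mapped into the unit box and perturbed with Gaussian
#' coordinate noise.  Regeneration with the same seed is bit-identical.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of spiral arms (>= 2).
#' @param noise_sd Gaussian coordinate noise s.d., in units of the unit box.
#' @param turns number of rotations each arm makes.
#' @param seed integer seed.
#' @param split tag stored with the dataset (`"train"`, `"validation"`,
#'   `"test"`).
#' @return a `labelled_dataset`: list with `inputs` (n x 2 matrix),
#'   `labels` (integers 1..n_classes), `one_hot` (n x n_classes matrix),
#'   `split`, and the generation parameters.
#' @export
generate_spirals <- function(n_per_class, n_classes = 4, noise_sd = 0.03,
                             turns = 0.5, seed = 1, split = "train") {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(proj_seed(seed, paste0("spirals/", split)))
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes), each = n_per_class)
  u <- stats::runif(n)            # position along the arm
  phi <- turns * 2 * pi * u
  ang <- phi + 2 * pi * (labels - 1) / n_classes
  r <- u
  x <- (r * cos(ang) + 1) / 2
  y <- (r * sin(ang) + 1) / 2
  if (noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, noise_sd)
    y <- y + stats::rnorm(n, 0, noise_sd)
  }
  inputs <- cbind(x, y)
  dimnames(inputs) <- NULL
  one_hot <- matrix(0, n, n_classes)
  one_hot[cbind(seq_len(n), labels)] <- 1
  structure(list(inputs = inputs, labels = labels, one_hot = one_hot,
                 split = split,
                 params = list(n_per_class = n_per_class,
                               n_classes = n_classes, noise_sd = noise_sd,
                               turns = turns, seed = seed)),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat("<labelled_dataset> ", nrow(x$inputs), " samples, ",
      ncol(x$inputs), " features, ", ncol(x$one_hot), " classes (",
      x$split, ")\n", sep = "")
  invisible(x)
}

read_idx_int <- function(con, n = 1) {
  v <- readBin(con, "integer", n = n, size = 4, endian = "big")
  if (length(v) < n) stop("IDX file truncated in header")
  v
}

#' Read an MNIST-style IDX image/label pair
#'
#' Parses the big-endian IDX binary format (magic 2051 for images, 2049 for
#' labels), flattens images row-major to feature vectors, and normalizes
#' pixel intensities to `[0, 1]`.  No files are downloaded; paths must point
#' at local copies.
#'
#' @param images_path path to an `idx3-ubyte` image file.
#' @param labels_path path to an `idx1-ubyte` label file.
#' @param split tag stored with the dataset.
#' @return a `labelled_dataset` with labels `1..10` (digit + 1) and digit
#'   one-hot columns ordered 0..9.
#' @export
read_mnist_idx <- function(images_path, labels_path, split = "test") {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- read_idx_int(con)
  if (magic != 2051)
    stop("bad magic number ", magic, " at offset 0 of ", images_path,
         " (expected 2051)")
  n <- read_idx_int(con)
  nr <- read_idx_int(con)
  nc <- read_idx_int(con)
  raw_px <- readBin(con, "integer", n = n * nr * nc, size = 1, signed = FALSE)
  if (length(raw_px) < n * nr * nc)
    stop("IDX image file truncated at offset ", 16 + length(raw_px))
  inputs <- matrix(raw_px / 255, nrow = n, ncol = nr * nc, byrow = TRUE)

  lcon <- file(labels_path, "rb")
  on.exit(close(lcon), add = TRUE)
  lmagic <- read_idx_int(lcon)
  if (lmagic != 2049)
    stop("bad magic number ", lmagic, " at offset 0 of ", labels_path,
         " (expected 2049)")
  nl <- read_idx_int(lcon)
  if (nl != n) stop("image/label counts differ: ", n, " vs ", nl)
  digits <- readBin(lcon, "integer", n = nl, size = 1, signed = FALSE)
  if (length(digits) < nl)
    stop("IDX label file truncated at offset ", 8 + length(digits))
  labels <- digits + 1L
  one_hot <- matrix(0, n, 10)
  one_hot[cbind(seq_len(n), labels)] <- 1
  structure(list(inputs = inputs, labels = labels, one_hot = one_hot,
                 split = split,
                 params = list(images_path = images_path,
                               labels_path = labels_path,
                               image_dim = c(nr, nc))),
            class = "labelled_dataset")
}

#' Write an IDX image/label pair (for fixtures and round-trip tests)
#'
#' @param dataset a `labelled_dataset` whose inputs are pixel intensities in
#'   `[0, 1]` and whose `params$image_dim` gives the image shape.
#' @param images_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_mnist_idx <- function(dataset, images_path, labels_path) {
  dim2 <- dataset$params$image_dim
  if (is.null(dim2)) stop("dataset has no image_dim; cannot write IDX")
  n <- nrow(dataset$inputs)
  con <- file(images_path, "wb")
  writeBin(c(2051L, n, dim2[1], dim2[2]), con, size = 4, endian = "big")
  px <- as.integer(round(t(dataset$inputs) * 255))
  writeBin(as.raw(px), con)
  close(con)
  lcon <- file(labels_path, "wb")
  writeBin(c(2049L, n), lcon, size = 4, endian = "big")
  writeBin(as.raw(dataset$labels - 1L), lcon)
  close(lcon)
  invisible(c(images_path, labels_path))
}

#' Deterministic tiny fixture networks with matching toy stimuli
#'
#' Small networks (at most 10 units per population) used as oracle test
#' beds:
#' \describe{
#'   \item{feedforward_tiny}{3-4-2 purely feedforward excitatory chain with
#'     symmetric top-down weights and exact dendritic cancellation; in this
#'     configuration the small-nudge dendritic updates coincide with the
#'     gradient.}
#'   \item{ei_tiny}{adds soma-targeting interneurons and lateral/recurrent
#'     inhibition.}
#'   \item{dendritic_tiny}{full dendritic architecture: E, SomaI, DendI
#'     populations in two hidden layers, top-down B projections and
#'     dendrite-targeting inhibition.}
#' }
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @param n_stimuli number of toy stimuli to generate.
#' @param ... passed on to [build_network()] (e.g. learning rates,
#'   `nudge_scale`).
#' @return list with `net` (a built network) and `stimuli` (list with
#'   `inputs`, `one_hot`, `labels`).
#' @export
make_fixture <- function(kind = c("feedforward_tiny", "ei_tiny",
                                  "dendritic_tiny"),
                         seed = 1, n_stimuli = 6, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  spec <- switch(kind, feedforward_tiny = {
    list(
      populations = list(
        population("Input", 0, "Input", 3),
        population("E1", 1, "E", 4, dendrite = TRUE),
        population("E2", 2, "E", 2, dendrite = TRUE)),
      projections = list(
        projection("Input", "E1", "W", w_init = 2, rule = "lds", eta = 0.1),
        projection("E1", "E2", "W", w_init = 2, rule = "lds", eta = 0.1),
        projection("E2", "E1", "B", target = "dendrite", w_init = 1)),
      symmetric_b = TRUE, b_scale = 1, exact_cancellation = TRUE)
  }, ei_tiny = {
    list(
      populations = list(
        population("Input", 0, "Input", 3),
        population("E1", 1, "E", 5),
        population("SomaI1", 1, "SomaI", 3),
        population("E2", 2, "E", 2),
        population("SomaI2", 2, "SomaI", 2)),
      projections = list(
        projection("Input", "E1", "W", w_init = 2),
        projection("Input", "SomaI1", "W", w_init = 1),
        projection("SomaI1", "E1", "Y", sign = -1, w_init = 1),
        projection("E1", "SomaI1", "Q", w_init = 1),
        projection("SomaI1", "SomaI1", "R", sign = -1, w_init = 0.5),
        projection("E1", "E2", "W", w_init = 2),
        projection("E1", "SomaI2", "W", w_init = 1),
        projection("SomaI2", "E2", "Y", sign = -1, w_init = 1),
        projection("E2", "SomaI2", "Q", w_init = 1),
        projection("SomaI2", "SomaI2", "R", sign = -1, w_init = 0.5)))
  }, dendritic_tiny = {
    list(
      populations = list(
        population("Input", 0, "Input", 3),
        population("E1", 1, "E", 6, dendrite = TRUE, bias = TRUE,
                   eta_bias = 0.05),
        population("SomaI1", 1, "SomaI", 3),
        population("DendI1", 1, "DendI", 3),
        population("E2", 2, "E", 5, dendrite = TRUE, bias = TRUE,
                   eta_bias = 0.05),
        population("SomaI2", 2, "SomaI", 2),
        population("DendI2", 2, "DendI", 2),
        population("E3", 3, "E", 4, dendrite = TRUE),
        population("SomaI3", 3, "SomaI", 2)),
      projections = list(
        projection("Input", "E1", "W", w_init = 2, rule = "lds", eta = 0.1),
        projection("Input", "SomaI1", "W", w_init = 0.5),
        projection("SomaI1", "E1", "Y", sign = -1, w_init = 0.5),
        projection("E1", "SomaI1", "Q", w_init = 0.5),
        projection("SomaI1", "SomaI1", "R", sign = -1, w_init = 0.25),
        projection("E1", "DendI1", "Q", w_init = 0.5, rule = "hebb_norm",
                   eta = 0.05, norm_total = 1),
        projection("DendI1", "DendI1", "R", sign = -1, w_init = 0.25),
        projection("DendI1", "E1", "Y", sign = -1, target = "dendrite",
                   w_init = 0.5, rule = "dend_inhib", eta = 0.05),
        projection("E2", "E1", "B", target = "dendrite", w_init = 0.5),
        projection("E1", "E2", "W", w_init = 2, rule = "lds", eta = 0.1),
        projection("E1", "SomaI2", "W", w_init = 0.5),
        projection("SomaI2", "E2", "Y", sign = -1, w_init = 0.5),
        projection("E2", "SomaI2", "Q", w_init = 0.5),
        projection("SomaI2", "SomaI2", "R", sign = -1, w_init = 0.25),
        projection("E2", "DendI2", "Q", w_init = 0.5, rule = "hebb_norm",
                   eta = 0.05, norm_total = 1),
        projection("DendI2", "DendI2", "R", sign = -1, w_init = 0.25),
        projection("DendI2", "E2", "Y", sign = -1, target = "dendrite",
                   w_init = 0.5, rule = "dend_inhib", eta = 0.05),
        projection("E3", "E2", "B", target = "dendrite", w_init = 0.5),
        projection("E2", "E3", "W", w_init = 2, rule = "lds", eta = 0.1),
        projection("E2", "SomaI3", "W", w_init = 0.5),
        projection("SomaI3", "E3", "Y", sign = -1, w_init = 0.5),
        projection("E3", "SomaI3", "Q", w_init = 0.5),
        projection("SomaI3", "SomaI3", "R", sign = -1, w_init = 0.25)),
      symmetric_b = TRUE, b_scale = 0.5)
  })
  build_args <- utils::modifyList(
    c(spec[setdiff(names(spec), c("populations", "projections"))],
      list(seed = seed)),
    args)
  net <- do.call(build_network, c(list(populations = spec$populations,
                                       projections = spec$projections),
                                  build_args))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(proj_seed(seed, paste0("fixture/", kind)))
  n_in <- net$pops[["Input"]]$size
  out_pop <- names(net$pops)[net$plan$types == "E" & net$plan$layers == net$L]
  n_out <- net$pops[[out_pop]]$size
  inputs <- matrix(stats::runif(n_stimuli * n_in), n_stimuli, n_in)
  labels <- sample.int(n_out, n_stimuli, replace = TRUE)
  one_hot <- matrix(0, n_stimuli, n_out)
  one_hot[cbind(seq_len(n_stimuli), labels)] <- 1
  list(net = net,
       stimuli = list(inputs = inputs, labels = labels, one_hot = one_hot))
}
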