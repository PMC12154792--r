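# Selectivity, Moran's I, receptive fields, alignment angles, accuracy.

test_that("selectivity hits its analytic edge cases", {
  expect_equal(selectivity(c(1, 1, 1, 1)), 0)
  expect_equal(selectivity(c(1, 0, 0, 0)), 1)
  expect_equal(selectivity(c(1, 1, 0, 0)), 2 / 3)
  # invariant to positive rescaling
  r <- c(0.2, 1.7, 0.3, 0.9, 0)
  expect_equal(selectivity(r), selectivity(7.3 * r))
  expect_true(is.na(selectivity(c(0, 0, 0))))
  expect_error(selectivity(1), "at least 2")
  expect_error(selectivity(c(-1, 1)), "nonnegative")
})

test_that("Moran's I matches a literal double-sum on rook neighbours", {
  expect_equal(morans_i(matrix(c(1, 0, 0, 1), 2, 2)), -1)
  expect_true(is.na(morans_i(matrix(5, 3, 3))))
  expect_error(morans_i(matrix(1, 1, 1)), "single pixel")

  oracle <- function(img) {
    nr <- nrow(img); nc <- ncol(img); N <- nr * nc
    xc <- img - mean(img)
    num <- 0; W <- 0
    for (i1 in 1:nr) for (j1 in 1:nc) for (i2 in 1:nr) for (j2 in 1:nc) {
      w <- as.numeric(abs(i1 - i2) + abs(j1 - j2) == 1)
      num <- num + w * xc[i1, j1] * xc[i2, j2]
      W <- W + w
    }
    (N / W) * num / sum(xc^2)
  }
  set.seed(9)
  for (i in 1:5) {
    img <- matrix(rnorm(30), 5, 6)
    expect_equal(morans_i(img), oracle(img), tolerance = 1e-12)
  }
  # affine invariance
  img <- matrix(runif(49), 7, 7)
  expect_equal(morans_i(3.2 * img + 5), morans_i(img), tolerance = 1e-12)
})

test_that("Moran's I is near zero for unstructured images and high for smooth ones", {
  set.seed(11)
  vals <- replicate(100, morans_i(matrix(rnorm(28 * 28), 28, 28)))
  expect_lt(abs(mean(vals)), 0.02)
  smooth <- outer(sin(seq(0, pi, length.out = 28)),
                  sin(seq(0, pi, length.out = 28)))
  expect_gt(morans_i(smooth), 0.9)
})

test_that("alignment angle hits its edge cases and is scale invariant", {
  U <- matrix(c(1, 2, -1, 0.5), 2, 2)
  expect_equal(alignment_angle(U, U), 0)
  expect_equal(alignment_angle(U, -U), 180)
  expect_equal(alignment_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(alignment_angle(2.5 * U, 0.3 * U), 0)
  V <- matrix(rnorm(4), 2, 2)
  expect_equal(alignment_angle(3 * U, 7 * V), alignment_angle(U, V))
  expect_true(is.na(alignment_angle(U, 0 * U)))
})

test_that("gradient receptive fields recover weights of a linear unit and pass FD", {
  net <- build_network(
    list(population("Input", 0, "Input", 4), population("E1", 1, "E", 1)),
    list(projection("Input", "E1", "W", w_init = 2)), seed = 3)
  w <- as.vector(get_weights(net, "Input->E1"))
  imgs <- matrix(runif(12, 0.2, 1), 3, 4)
  map <- receptive_field(net, "E1", 1, imgs)
  expect_equal(map, w / max(abs(w)), tolerance = 1e-8)

  # silent unit: zero map
  net0 <- net; net0$projs[[1]]$W[] <- 0
  expect_equal(receptive_field(net0, "E1", 1, imgs), rep(0, 4))

  # recurrent fixture against central differences on the truncated window
  fx <- make_fixture("ei_tiny", seed = 6)
  netr <- fx$net
  x <- fx$stimuli$inputs[1, ]
  k <- 3
  eq <- equilibrate(netr, x, retain_history = TRUE)
  TT <- length(eq$history)
  start <- eq$history[[TT - k]]
  unit <- 2
  i2 <- netr$plan$idx[["E2"]]
  map <- receptive_field(netr, "E2", unit, matrix(x, 1), normalize = FALSE)
  for (j in seq_along(x)) {
    h <- 1e-5
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    fp <- eiann:::truncated_forward(netr, start, xp, k)$A[[i2]][unit]
    fm <- eiann:::truncated_forward(netr, start, xm, k)$A[[i2]][unit]
    fd <- (fp - fm) / (2 * h)
    expect_equal(map[j], fd, tolerance = 1e-4)
  }
  expect_error(receptive_field(netr, "E2", 99, matrix(x, 1)), "out of range")
})

test_that("accuracy scores argmax predictions deterministically", {
  # oracle network: identity readout of a one-hot input
  net <- build_network(
    list(population("Input", 0, "Input", 4), population("E1", 1, "E", 4)),
    list(projection("Input", "E1", "W", w_init = 1)))
  net$projs[[1]]$W <- diag(4)
  ds <- structure(list(inputs = diag(4), labels = 1:4,
                       one_hot = diag(4), split = "test"),
                  class = "labelled_dataset")
  expect_equal(evaluate_accuracy(net, ds), 100)

  one <- structure(list(inputs = diag(4)[1, , drop = FALSE], labels = 2L,
                        one_hot = diag(4)[2, , drop = FALSE], split = "test"),
                   class = "labelled_dataset")
  expect_true(evaluate_accuracy(net, one) %in% c(0, 100))

  # untrained networks sit near chance over seeds
  val <- generate_spirals(25, 4, seed = 31, split = "validation")
  accs <- vapply(1:5, function(s) {
    fx <- make_fixture("dendritic_tiny", seed = s)
    net <- fx$net
    # reshape input layer to 2 features by trimming
    evaluate_accuracy(spirals_network("dendritic_lds", seed = s), val)
  }, 0)
  expect_gt(mean(accs), 5)
  expect_lt(mean(accs), 55)
})

test_that("per-unit selectivity table is well-formed on a tiny network", {
  fx <- make_fixture("dendritic_tiny", seed = 2)
  ds <- structure(list(inputs = fx$stimuli$inputs,
                       labels = fx$stimuli$labels,
                       one_hot = fx$stimuli$one_hot, split = "validation"),
                  class = "labelled_dataset")
  tab <- population_selectivity(fx$net, ds, pops = c("E1", "DendI1"))
  expect_equal(nrow(tab), fx$net$pops$E1$size + fx$net$pops$DendI1$size)
  ok <- !is.na(tab$selectivity)
  expect_true(all(tab$selectivity[ok] >= -1e-9 & tab$selectivity[ok] <= 1 + 1e-9))
})
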