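# Learning rules: direct-evaluation oracles, normalization identities,
# trace dynamics, and the gradient limit.

test_that("LDS update is dendritic state x gate x presynaptic activity", {
  net <- pair_net()
  tr0 <- stub_trial(net, dhat = list(E1 = 0), sens_A = list(Input = 2))
  expect_equal(lds_update(tr0, net, "Input->E1"), matrix(0, 1, 1))

  tr <- stub_trial(net, dhat = list(E1 = 0.5), sens_A = list(Input = 2))
  expect_equal(lds_update(tr, net, "Input->E1")[1, 1], 0.1)  # 0.1*0.5*1*2

  trg <- stub_trial(net, dhat = list(E1 = 0.5), sens_A = list(Input = 2),
                    sens_G = list(E1 = 0))
  expect_equal(lds_update(trg, net, "Input->E1")[1, 1], 0)
})

test_that("bias update is dendritic state x gate, scaled by its own rate", {
  net <- build_network(
    list(population("Input", 0, "Input", 1),
         population("E1", 1, "E", 1, dendrite = TRUE, bias = TRUE,
                    eta_bias = 0.5)),
    list(projection("Input", "E1", "W")))
  expect_equal(bias_update(stub_trial(net, dhat = list(E1 = 0)), net, "E1"), 0)
  expect_equal(bias_update(stub_trial(net, dhat = list(E1 = 1),
                                      sens_G = list(E1 = 0)), net, "E1"), 0)
  expect_equal(bias_update(stub_trial(net, dhat = list(E1 = -0.2)), net, "E1"),
               -0.1)
})

test_that("normalized Hebbian rule conserves per-row magnitude totals", {
  net <- pair_net(n_pre = 2, rule = "hebb_norm", eta = 0, norm_total = 2)
  net$projs[[1]]$W <- matrix(c(1, 3), 1, 2)
  tr <- stub_trial(net)
  expect_equal(hebb_norm_update(tr, net, "Input->E1"),
               matrix(c(0.5, 1.5), 1, 2))   # pure rescale

  # 2x2 toy against a literal transcription of the update + normalization
  net2 <- pair_net(n_pre = 2, n_post = 2, rule = "hebb_norm", eta = 0.5,
                   norm_total = 1.2)
  W <- matrix(c(0.2, 0.1, 0.4, 0.3), 2, 2)
  net2$projs[[1]]$W <- W
  a_pre <- c(1, 2); a_post <- c(0.5, 3)
  tr2 <- stub_trial(net2, sens_A = list(Input = a_pre, E1 = a_post))
  Wn <- W + 0.5 * outer(a_post, a_pre)
  Wn <- Wn * 1.2 / rowSums(abs(Wn))
  got <- hebb_norm_update(tr2, net2, "Input->E1")
  expect_equal(got, Wn, tolerance = 1e-12)
  expect_equal(rowSums(abs(got)), c(1.2, 1.2), tolerance = 1e-12)
})

test_that("inhibitory Hebbian normalization keeps the sign and the total", {
  net <- build_network(
    list(population("Input", 0, "Input", 1),
         population("E1", 1, "E", 2),
         population("SomaI1", 1, "SomaI", 2)),
    list(projection("Input", "E1", "W"),
         projection("Input", "SomaI1", "W"),
         projection("SomaI1", "E1", "Y", sign = -1, rule = "hebb_norm",
                    eta = 0.3, norm_total = 2)))
  tr <- stub_trial(net, sens_A = list(SomaI1 = c(1, 0.5), E1 = c(2, 1)))
  got <- hebb_norm_update(tr, net, "SomaI1->E1")
  expect_true(all(got <= 0))
  expect_equal(rowSums(abs(got)), c(2, 2), tolerance = 1e-12)
})

test_that("dendritic inhibition strengthens against dendritic depolarization", {
  net <- build_network(
    list(population("Input", 0, "Input", 1),
         population("E1", 1, "E", 1, dendrite = TRUE),
         population("DendI1", 1, "DendI", 1),
         population("E2", 2, "E", 1)),
    list(projection("Input", "E1", "W"),
         projection("E1", "DendI1", "Q"),
         projection("DendI1", "E1", "Y", sign = -1, target = "dendrite",
                    rule = "dend_inhib", eta = 0.1),
         projection("E1", "E2", "W")))
  nm <- "DendI1->E1"
  tr0 <- stub_trial(net, sens_D = list(E1 = 0), sens_A = list(DendI1 = 1))
  expect_equal(dend_inhib_update(tr0, net, nm), matrix(0, 1, 1))
  tr <- stub_trial(net, sens_D = list(E1 = 0.4), sens_A = list(DendI1 = 1))
  expect_equal(dend_inhib_update(tr, net, nm)[1, 1], -0.04)

  # with frozen activities, repeated application drives d to 0 monotonically
  b <- 0.5; a_di <- 1; y <- 0
  d_seq <- numeric(60)
  for (i in 1:60) {
    d <- b + y * a_di
    d_seq[i] <- d
    tr_i <- stub_trial(net, sens_D = list(E1 = d),
                       sens_A = list(DendI1 = a_di))
    y <- y + dend_inhib_update(tr_i, net, nm)[1, 1]
  }
  expect_true(all(diff(abs(d_seq)) <= 1e-12))
  expect_lt(abs(d_seq[60]), 1e-2)
})

test_that("TCH update is the cross-phase difference of activity products", {
  net <- pair_net(rule = "tch", eta = 1)
  tr0 <- stub_trial(net, sens_A = list(Input = 2, E1 = 1),
                    sup_A = list(Input = 2, E1 = 1))
  expect_equal(tch_update(tr0, net, "Input->E1"), matrix(0, 1, 1))
  tr <- stub_trial(net, sens_A = list(Input = 2, E1 = 1),
                   sup_A = list(Input = 2, E1 = 1.5))
  expect_equal(tch_update(tr, net, "Input->E1")[1, 1], 1)  # 1.5*2 - 1*2
})

test_that("TCH aligns better with LDS as the nudge scale shrinks", {
  # The temporal contrast recovers the dendritic term d_i * a_j plus
  # first-order presynaptic cross-terms, so the angle approaches a small
  # positive value rather than zero; in the mean over seeds it decreases
  # monotonically with the nudge scale.
  mean_angle <- function(sc) {
    mean(vapply(1:10, function(s) {
      fx <- make_fixture("dendritic_tiny", seed = s, nudge_scale = sc)
      tr <- run_trial(fx$net, fx$stimuli$inputs[1, ],
                      fx$stimuli$one_hot[1, ])
      alignment_angle(tch_update(tr, fx$net, "E1->E2"),
                      lds_update(tr, fx$net, "E1->E2"))
    }, 0))
  }
  angles <- vapply(c(0.5, 0.1, 0.02), mean_angle, 0)
  expect_true(all(diff(angles) < 0))
  expect_lt(angles[3], 90)   # positively aligned in the small-nudge limit
})

test_that("TCH equals LDS exactly for input projections without lateral feedback", {
  # with constant presynaptic input and no lateral inhibition the
  # supervised activity change is exactly dhat * gate, so the temporal
  # contrast reproduces the dendritic update up to the learning rates
  fx <- make_fixture("feedforward_tiny", seed = 5, nudge_scale = 0.2,
                     steps_per_phase = 120)   # both phases fully converged
  tr <- run_trial(fx$net, fx$stimuli$inputs[1, ], fx$stimuli$one_hot[1, ])
  expect_equal(tch_update(tr, fx$net, "Input->E1"),
               lds_update(tr, fx$net, "Input->E1"), tolerance = 1e-10)
})

test_that("BCM threshold gates potentiation and relaxes toward a~^2/k", {
  net <- pair_net(rule = "bcm", eta = 0.1, bcm_k = 2, bcm_tau_theta = 10)
  nm <- "Input->E1"
  tr <- stub_trial(net, sup_A = list(Input = 1, E1 = 0.7))
  r <- bcm_update(tr, net, nm, theta = 0.7)
  expect_equal(r$dW, matrix(0, 1, 1))     # at threshold: no change

  # constant a~ = 2, k = 2: theta converges to 2; matches scalar recursion
  theta <- 0
  theta_oracle <- 0
  tr2 <- stub_trial(net, sup_A = list(Input = 1, E1 = 2))
  for (i in 1:60) {
    r <- bcm_update(tr2, net, nm, theta = theta)
    theta <- r$theta
    theta_oracle <- theta_oracle + (-theta_oracle + 4 / 2) / 10
    expect_equal(theta, theta_oracle, tolerance = 1e-12)
  }
  expect_equal(theta, 2, tolerance = 0.05)
  # potentiation above threshold, depression below
  r_lo <- bcm_update(tr2, net, nm, theta = 3)
  expect_lt(r_lo$dW[1, 1], 0)
  r_hi <- bcm_update(tr2, net, nm, theta = 1)
  expect_gt(r_hi$dW[1, 1], 0)
})

test_that("BTSP saturating sigma meets its edge constraints", {
  expect_equal(btsp_sigma(0), 0)
  expect_equal(btsp_sigma(1), 1)
  expect_true(all(diff(btsp_sigma(seq(0, 1, 0.05))) >= 0))
})

test_that("BTSP potentiates toward w_max and matches a two-stimulus oracle", {
  net <- pair_net(rule = "btsp", eta = 1, w_max = 1, lambda = 0.3)
  nm <- "Input->E1"
  net$projs[[nm]]$W <- matrix(0, 1, 1)

  # no eligibility anywhere and nonnegative dendritic state: no update
  tr0 <- stub_trial(net, dhat = list(E1 = 0.5),
                    sup_A = list(Input = 0), sens_A = list(Input = 0))
  r0 <- btsp_update(tr0, net, nm,
                    traces = list(ET = 0, IS = 0, dg = 0))
  expect_equal(r0$dW, matrix(0, 1, 1))

  # w = 0, full eligibility, eta*dhat*g = 1: pure potentiation by w_max
  tr1 <- stub_trial(net, dhat = list(E1 = 1), sup_A = list(Input = 1))
  r1 <- btsp_update(tr1, net, nm, traces = list(ET = 0, IS = 0, dg = 0))
  expect_equal(r1$dW[1, 1], 1)            # w_max = 1, sigma(1) depresses w=0
  expect_equal(r1$traces$ET, 1)
  expect_equal(r1$traces$IS, 1)

  # two-stimulus sequence on a 1x1 projection, against a literal
  # transcription of the within- and cross-stimulus terms
  w <- 0.4; w_max <- 1; lam <- 0.3; eta <- 0.7
  net$projs[[nm]]$W <- matrix(w, 1, 1)
  net$projs[[nm]]$eta <- eta
  a1 <- 0.8; d1 <- 0.6     # stimulus 1
  a2 <- 0.5; d2 <- 0.9     # stimulus 2
  trA <- stub_trial(net, dhat = list(E1 = d1), sup_A = list(Input = a1))
  rA <- btsp_update(trA, net, nm, traces = list(ET = 0, IS = 0, dg = 0))
  oracle_A <- eta * d1 * ((w_max - w) * a1 * 1 - w * btsp_sigma(a1 * 1))
  expect_equal(rA$dW[1, 1], oracle_A, tolerance = 1e-12)

  trB <- stub_trial(net, dhat = list(E1 = d2), sup_A = list(Input = a2))
  rB <- btsp_update(trB, net, nm, traces = rA$traces)
  within <- eta * d2 * ((w_max - w) * a2 - w * btsp_sigma(a2))
  cross_et <- eta * d2 * ((w_max - w) * (lam * a1) - w * btsp_sigma(lam * a1))
  cross_is <- eta * d1 * ((w_max - w) * (a2 * lam) - w * btsp_sigma(a2 * lam))
  expect_equal(rB$dW[1, 1], within + cross_et + cross_is, tolerance = 1e-12)

  # negative dendritic state falls back to the LDS rule
  trC <- stub_trial(net, dhat = list(E1 = -0.5),
                    sens_A = list(Input = 0.9), sup_A = list(Input = 0.9))
  rC <- btsp_update(trC, net, nm, traces = list(ET = 0, IS = 0, dg = 0))
  expect_equal(rC$dW[1, 1], eta * (-0.5) * 0.9, tolerance = 1e-12)
  expect_equal(rC$traces$IS, 0)
})

test_that("BTSP weights stay inside [0, w_max] under the within-stimulus term", {
  net <- pair_net(n_pre = 4, n_post = 3, rule = "btsp", eta = 0.9,
                  w_max = 1.2, lambda = 0)
  nm <- "Input->E1"
  set.seed(33)
  for (i in 1:200) {
    W <- matrix(runif(12, 0, 1.2), 3, 4)
    net$projs[[nm]]$W <- W
    tr <- stub_trial(net, dhat = list(E1 = runif(3)),
                     sup_A = list(Input = runif(4, 0, 2)))
    r <- btsp_update(tr, net, nm, traces = list(ET = numeric(4),
                                                IS = numeric(3),
                                                dg = numeric(3)))
    Wn <- W + r$dW
    expect_true(all(Wn >= -1e-12 & Wn <= 1.2 + 1e-12))
  }
})

test_that("learned top-down weights renormalize per postsynaptic neuron", {
  net <- build_network(
    list(population("Input", 0, "Input", 1),
         population("E1", 1, "E", 3, dendrite = TRUE),
         population("DendI1", 1, "DendI", 1),
         population("E2", 2, "E", 2)),
    list(projection("Input", "E1", "W"),
         projection("E1", "DendI1", "Q"),
         projection("DendI1", "E1", "Y", sign = -1, target = "dendrite"),
         projection("E2", "E1", "B", target = "dendrite", rule = "topdown_tch",
                    eta = 0.4, norm_total = 1.5),
         projection("E1", "E2", "W")))
  nm <- "E2->E1"
  a1 <- c(0.2, 0.6, 0.1); a2 <- c(0.5, 0.3); a2_sup <- c(0.9, 0.1)
  tr <- stub_trial(net, sens_A = list(E1 = a1, E2 = a2),
                   sup_A = list(E2 = a2_sup))
  got <- topdown_tch_update(tr, net, nm)
  W <- get_weights(net, nm)
  Wn <- pmax(W + 0.4 * outer(a1, a2_sup - a2), 0)
  Wn <- Wn * 1.5 / rowSums(Wn)
  expect_equal(got, Wn, tolerance = 1e-12)
  expect_equal(rowSums(got), rep(1.5, 3), tolerance = 1e-12)
  expect_true(all(got >= 0))

  # zero activity change: renormalization only
  tr0 <- stub_trial(net, sens_A = list(E1 = a1, E2 = a2),
                    sup_A = list(E2 = a2))
  expect_equal(topdown_tch_update(tr0, net, nm),
               W * 1.5 / rowSums(W), tolerance = 1e-12)
})

test_that("update application clamps signs, diagonals, and rejects non-finite deltas", {
  fx <- make_fixture("dendritic_tiny", seed = 3)
  net <- fx$net
  before <- lapply(net$projs, `[[`, "W")
  expect_identical(lapply(apply_updates(net, list())$projs, `[[`, "W"), before)

  nm <- "Input->E1"
  big_neg <- list(projs = stats::setNames(
    list(list(kind = "delta", value = -1e3 * (1 + abs(before[[nm]])))), nm))
  net2 <- apply_updates(net, big_neg)
  expect_true(all(get_weights(net2, nm) == 0))

  rec <- "SomaI1->SomaI1"
  bump <- list(projs = stats::setNames(
    list(list(kind = "delta", value = matrix(-1, 3, 3))), rec))
  net3 <- apply_updates(net, bump)
  expect_equal(diag(get_weights(net3, rec)), rep(0, 3))

  bad <- list(projs = stats::setNames(
    list(list(kind = "delta", value = matrix(NaN, 6, 3))), nm))
  expect_error(apply_updates(net, bad), "non-finite")
})

test_that("rules are pure: identical trial and traces give identical deltas", {
  fx <- make_fixture("dendritic_tiny", seed = 14)
  tr <- run_trial(fx$net, fx$stimuli$inputs[1, ], fx$stimuli$one_hot[1, ])
  d1 <- compute_trial_updates(tr, fx$net)
  d2 <- compute_trial_updates(tr, fx$net)
  expect_identical(d1, d2)
})

test_that("LDS matches the gradient in the feedforward symmetric limit", {
  fx <- make_fixture("feedforward_tiny", seed = 17, nudge_scale = 0.05)
  tr <- run_trial(fx$net, fx$stimuli$inputs[1, ], fx$stimuli$one_hot[1, ],
                  retain_history = TRUE)
  bp <- backprop_baseline(tr, fx$net, "global_mse", k = 3)
  for (nm in c("Input->E1", "E1->E2")) {
    ang <- alignment_angle(lds_update(tr, fx$net, nm), -bp$W[[nm]])
    expect_lt(ang, 1)
  }
})
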