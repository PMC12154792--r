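# Training and evaluation harness: per-stimulus trial -> rule dispatch ->
# atomic update application -> periodic metrics.

#' Train a network on a labelled dataset
#'
#' Stimuli are presented one at a time (batch size 1) in a seed-specific
#' shuffled order, one weight update per stimulus.  Each stimulus runs the
#' full two-phase trial protocol; all bound learning rules are dispatched on
#' the frozen trial record and applied atomically.
#'
#' @param net a built `eiann_network`.
#' @param data a `labelled_dataset`.
#' @param epochs number of passes over the data.
#' @param seed integer seed controlling the presentation order.
#' @param shuffle present stimuli in shuffled order (per epoch).
#' @param eval_data optional `labelled_dataset` scored at `metrics_every`.
#' @param metrics_every evaluate accuracy every this many stimuli
#'   (0 = never).
#' @param bptt_steps truncation window for backpropagation-bound rules.
#' @param verbose print progress.
#' @return list with `net` (trained), `metrics` (data frame of cadence
#'   accuracies) and `dend_mag` (per-stimulus mean absolute sensory
#'   dendritic state of hidden E cells, `NA` for non-dendritic networks).
#' @export
train_network <- function(net, data, epochs = 1, seed = 1, shuffle = TRUE,
                          eval_data = NULL, metrics_every = 0,
                          bptt_steps = 3, verbose = FALSE) {
  n <- nrow(data$inputs)
  rules <- vapply(net$projs, `[[`, "", "rule")
  needs_history <- any(rules %in% c("backprop", "backprop_local"))
  phases <- vapply(net$projs, `[[`, "", "phase")
  needs_supervised <- any(rules %in% c("tch", "bcm", "btsp", "topdown_tch")) ||
    any(rules == "hebb_norm" & phases == "supervised")
  plan <- net$plan
  hidden_dend <- which(plan$types == "E" & plan$dendritic &
                         plan$layers < net$L)
  dend_mag <- numeric(0)
  metrics <- list()
  presented <- 0L
  for (e in seq_len(epochs)) {
    ord <- seq_len(n)
    if (shuffle) {
      old <- .Random.seed_save()
      set.seed(proj_seed(seed, paste0("train/epoch", e)))
      ord <- sample.int(n)
      .Random.seed_restore(old)
    }
    for (i in ord) {
      trial <- run_trial(net, data$inputs[i, ], data$one_hot[i, ],
                         retain_history = needs_history,
                         supervised = needs_supervised)
      deltas <- compute_trial_updates(trial, net, bptt_steps = bptt_steps)
      net <- apply_updates(net, deltas)
      presented <- presented + 1L
      dend_mag[presented] <- if (length(hidden_dend))
        mean(unlist(lapply(trial$sens$D[hidden_dend], abs))) else NA_real_
      if (metrics_every > 0 && !is.null(eval_data) &&
          presented %% metrics_every == 0) {
        acc <- evaluate_accuracy(net, eval_data)
        metrics[[length(metrics) + 1L]] <-
          data.frame(stimulus = presented, accuracy = acc)
        if (verbose)
          message("stimulus ", presented, ": accuracy ", round(acc, 2), "%")
      }
    }
  }
  list(net = net,
       metrics = if (length(metrics)) do.call(rbind, metrics)
                 else data.frame(stimulus = integer(0), accuracy = numeric(0)),
       dend_mag = dend_mag)
}

#' Train several independently seeded instances
#'
#' Builds one network per seed with `builder(seed)`, trains each on the
#' same samples in a seed-specific shuffled order, and reports the
#' across-seed mean and standard deviation of validation accuracy.
#'
#' @param builder function of one argument (the seed) returning a built
#'   network.
#' @param data training `labelled_dataset`.
#' @param eval_data validation `labelled_dataset`.
#' @param seeds integer vector of seeds (one instance per seed).
#' @param ... passed to [train_network()].
#' @return list with `accuracy` (per-seed vector), `mean`, `sd`, and
#'   `runs` (per-seed training results).
#' @export
train_instances <- function(builder, data, eval_data, seeds = 1:5, ...) {
  runs <- lapply(seeds, function(s) {
    res <- train_network(builder(s), data, seed = s, ...)
    res$accuracy <- evaluate_accuracy(res$net, eval_data)
    res
  })
  acc <- vapply(runs, `[[`, 0, "accuracy")
  list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc), runs = runs)
}

#' Compare a rule's prescribed updates with the gradient
#'
#' For each selected sample, runs one two-phase trial, computes the bound
#' rule's update and the truncated-backpropagation update on the same trial
#' record, and reports the alignment angle per bottom-up excitatory
#' projection.  Also reports, per top-down projection, the angle between
#' `B` and the transpose of the corresponding bottom-up weights.
#'
#' @param net a built network.
#' @param data a `labelled_dataset`.
#' @param samples row indices to use.
#' @param k truncation window for the backward pass.
#' @return data frame with columns `sample`, `projection`, `comparison`
#'   (`"update_vs_gradient"` or `"B_vs_Wt"`), `angle`.
#' @export
compare_to_backprop <- function(net, data, samples = 1, k = 3) {
  rules <- vapply(net$projs, `[[`, "", "rule")
  rows <- list()
  for (i in samples) {
    trial <- run_trial(net, data$inputs[i, ], data$one_hot[i, ],
                       retain_history = TRUE)
    bp <- backprop_baseline(trial, net, mode = "global_mse", k = k)
    deltas <- compute_trial_updates(trial, net, bptt_steps = k)
    for (nm in names(net$projs)) {
      p <- net$projs[[nm]]
      if (p$direction != "W" || !rules[[nm]] %in%
            c("lds", "tch", "bcm", "btsp", "backprop")) next
      if (!net$pops[[p$post]]$type == "E") next
      upd <- deltas$projs[[nm]]
      if (is.null(upd)) next
      dW <- if (identical(upd$kind, "replace")) upd$value - p$W else upd$value
      rows[[length(rows) + 1L]] <- data.frame(
        sample = i, projection = nm, comparison = "update_vs_gradient",
        angle = alignment_angle(dW, -bp$W[[nm]]))
    }
  }
  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    if (p$direction != "B") next
    up <- find_projection(net, pre = p$post, post = p$pre, direction = "W")
    if (is.null(up)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sample = NA_integer_, projection = nm, comparison = "B_vs_Wt",
      angle = alignment_angle(p$W, t(net$projs[[up]]$W)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Angle between top-down weights and the bottom-up transpose
#'
#' @param net a built network.
#' @return named vector of angles (degrees), one per top-down projection.
#' @export
b_w_alignment <- function(net) {
  angles <- c()
  for (nm in names(net$projs)) {
    p <- net$projs[[nm]]
    if (p$direction != "B") next
    up <- find_projection(net, pre = p$post, post = p$pre, direction = "W")
    if (is.null(up)) next
    angles[nm] <- alignment_angle(p$W, t(net$projs[[up]]$W))
  }
  angles
}
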