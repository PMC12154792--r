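# Structured text configuration files (YAML): architecture, projections
# with rule bindings, dynamics constants.  Checkpoints are self-describing
# RDS containers with a version tag.

#' Read a network configuration file
#'
#' The YAML schema mirrors [population()] and [projection()]:
#' top-level keys `tau`, `steps_per_phase`, `dendrite_clip`,
#' `symmetric_b`, `b_scale`, `exact_cancellation`,
#' `clamp_activity_nonneg`, `nudge_scale`, plus `populations:` and
#' `projections:` lists whose entries hold the corresponding constructor
#' arguments.
#'
#' @param path YAML file path.
#' @param seed integer seed for weight initialization.
#' @return a built `eiann_network`.
#' @export
read_network_config <- function(path, seed = 1) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$populations) || is.null(cfg$projections))
    stop("config must contain 'populations' and 'projections'")
  pops <- lapply(cfg$populations, function(p) do.call(population, p))
  projs <- lapply(cfg$projections, function(p) do.call(projection, p))
  top <- cfg[setdiff(names(cfg), c("populations", "projections"))]
  do.call(build_network, c(list(populations = pops, projections = projs,
                                seed = seed), top))
}

#' Save a trained network to a checkpoint container
#'
#' @param net an `eiann_network`.
#' @param path output file path.
#' @param metadata optional list stored alongside the network.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(net, path, metadata = list()) {
  obj <- list(format = "eiann_checkpoint", version = 1L,
              created = format(Sys.time(), tz = "UTC"),
              metadata = metadata,
              net = net[setdiff(names(net), "plan")])
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network from a checkpoint container
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return the restored `eiann_network`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "eiann_checkpoint"))
    stop(path, " is not an eiann checkpoint")
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package")
  net <- structure(obj$net, class = "eiann_network")
  net$plan <- build_plan(net)
  net
}

#' Export a labelled dataset as delimited text
#'
#' @param dataset a `labelled_dataset`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_dataset_tsv <- function(dataset, path) {
  df <- as.data.frame(dataset$inputs)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$label <- dataset$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
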