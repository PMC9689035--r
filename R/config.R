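#' Composite run configuration
#'
#' Bundles every configurable component of a run — neuron dynamics, encoder,
#' network topology, training loop, augmentation policy, synthetic generator
#' and file paths — under a single seed. The composite round-trips losslessly
#' to YAML via \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param neuron a \code{\link{neuron_params}}.
#' @param network a \code{\link{network_config}}; its neuron/encoder are kept
#'   consistent with \code{neuron}.
#' @param train a \code{\link{train_config}}.
#' @param augment an \code{\link{augment_policy}}.
#' @param synth a \code{\link{synth_config}}.
#' @param paths named list of file paths (free-form strings).
#' @param seed master seed; when non-NULL it overwrites the seeds of the
#'   training, augmentation and synthetic components so that one integer
#'   governs all randomness.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(neuron = neuron_params(),
                       network = NULL,
                       train = train_config(),
                       augment = augment_policy(),
                       synth = synth_config(),
                       paths = list(),
                       seed = 1) {
  if (is.null(network)) network <- network_config(neuron = neuron)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    train$seed <- seed
    augment$seed <- seed
    synth$seed <- seed
  }
  structure(list(neuron = neuron, network = network, train = train,
                 augment = augment, synth = synth, paths = paths,
                 seed = seed),
            class = "run_config")
}

# Strip classes/functions so yaml serialises plain scalars and vectors.
.plain <- function(x) {
  x <- unclass(x)
  x[!vapply(x, function(v) is.function(v) || is.list(v), logical(1))]
}

#' Write a run configuration to YAML
#'
#' @param cfg a \code{\link{run_config}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  doc <- list(
    seed = cfg$seed,
    neuron = .plain(cfg$neuron),
    encoder = .plain(cfg$network$encoder),
    network = .plain(cfg$network),
    train = .plain(cfg$train),
    augment = .plain(cfg$augment),
    synth = .plain(cfg$synth),
    paths = cfg$paths)
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

# Call a constructor with only the arguments it knows, validating the rest.
.rebuild <- function(ctor, fields, extra = list()) {
  if (is.null(fields)) fields <- list()
  keep <- fields[names(fields) %in% names(formals(ctor))]
  do.call(ctor, c(keep, extra))
}

#' Read a run configuration from YAML
#'
#' Reconstructs every component through its validating constructor, so a
#' malformed file fails loudly rather than silently.
#'
#' @param path YAML file written by \code{\link{write_config}} (or hand
#'   authored with the same keys).
#' @return a \code{\link{run_config}}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  neuron <- .rebuild(neuron_params, doc$neuron)
  encoder <- .rebuild(encoder_config, doc$encoder, list(neuron = neuron))
  network <- .rebuild(network_config, doc$network,
                      list(neuron = neuron, encoder = encoder))
  run_config(neuron = neuron, network = network,
             train = .rebuild(train_config, doc$train),
             augment = .rebuild(augment_policy, doc$augment),
             synth = .rebuild(synth_config, doc$synth),
             paths = if (is.null(doc$paths)) list() else doc$paths,
             seed = doc$seed)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (seed ", x$seed, ")\n", sep = "")
  cat("  neuron:  mode ", x$neuron$mode, ", Vth ", x$neuron$v_th,
      ", a1 ", x$neuron$a1, "\n", sep = "")
  cat("  network: T ", x$network$t_steps, ", plan ",
      paste(x$network$channel_plan, collapse = "/"), "\n", sep = "")
  cat("  train:   lr ", x$train$lr, ", epochs ", x$train$epochs,
      ", batch ", x$train$batch_size, "\n", sep = "")
  cat("  synth:   ", x$synth$n_images, " images of ", x$synth$size, "x",
      x$synth$size, "\n", sep = "")
  invisible(x)
}
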