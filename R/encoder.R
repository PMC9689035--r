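#' Spike encoder configuration
#'
#' The encoder turns a real-valued RGB image into a binary spike train: two
#' stacked same-padded convolutions (no intermediate nonlinearity) produce a
#' static current map that drives an RGC layer at every simulation step. The
#' encoder's convolution weights are trained jointly with the rest of the
#' network.
#'
#' @param in_channels number of image channels (3 for RGB).
#' @param out_channels number of current/feature channels (24 in the full-scale
#'   network).
#' @param kernel odd kernel size; padding preserves the spatial size.
#' @param t_steps number of simulation time steps.
#' @param neuron a \code{\link{neuron_params}} object.
#' @return An object of class \code{encoder_config}.
#' @export
encoder_config <- function(in_channels = 3, out_channels = 24, kernel = 7,
                           t_steps = 8, neuron = neuron_params()) {
  stopifnot(kernel %% 2 == 1, in_channels >= 1, out_channels >= 1, t_steps >= 1)
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 kernel = kernel, t_steps = t_steps, neuron = neuron),
            class = "encoder_config")
}

#' Spike train container
#'
#' A binary activation tensor over simulation time, stored as a list of
#' \code{t_steps} pixel-by-channel matrices. Use \code{\link{as.array.spike_train}}
#' to obtain the dense \code{[T, C, H, W]} array.
#'
#' @param values list of T binary (H*W) x C matrices.
#' @param H,W spatial dimensions.
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(values, H, W) {
  stopifnot(length(values) >= 1)
  for (v in values)
    if (any(v != 0 & v != 1)) stop("spike train values must be binary")
  structure(list(values = values, t_steps = length(values),
                 H = H, W = W, C = ncol(values[[1]])),
            class = "spike_train")
}

#' @rdname spike_train
#' @param x a \code{spike_train}.
#' @param ... unused.
#' @export
as.array.spike_train <- function(x, ...) {
  out <- array(0, c(x$t_steps, x$C, x$H, x$W))
  for (t in seq_len(x$t_steps)) {
    a <- array(x$values[[t]], c(x$H, x$W, x$C))       # H, W, C
    out[t, , , ] <- aperm(a, c(3L, 1L, 2L))
  }
  out
}

#' Build randomly initialised encoder weights
#'
#' @param cfg an \code{\link{encoder_config}}.
#' @return list with \code{enc1} and \code{enc2}, each a list of a weight
#'   matrix \code{w} and bias vector \code{b}.
#' @export
build_encoder <- function(cfg) {
  k <- cfg$kernel
  list(enc1 = init_conv(k, cfg$in_channels, cfg$out_channels),
       enc2 = init_conv(k, cfg$out_channels, cfg$out_channels))
}

#' Encode an image into a spike train
#'
#' Applies the two encoder convolutions to obtain a static current map and
#' injects that same map into an RGC layer at every one of the \code{t_steps}
#' simulation steps; the per-step spike maps form the output train. Spatial
#' size is preserved.
#'
#' @param image an H x W x C array with values in [0, 1] (values outside the
#'   range trigger a warning), or an (H*W) x C matrix with attributes
#'   \code{H}, \code{W}.
#' @param weights encoder weights as returned by the internal builder or taken
#'   from a fitted model (\code{list(enc1 = list(w, b), enc2 = list(w, b))}).
#' @param cfg an \code{\link{encoder_config}}.
#' @return A \code{\link{spike_train}} with \code{t_steps} leading steps and
#'   \code{out_channels} channels.
#' @export
encode <- function(image, weights, cfg = encoder_config()) {
  if (is.array(image) && length(dim(image)) == 3) {
    H <- dim(image)[1]; W <- dim(image)[2]
    x <- matrix(image, H * W, dim(image)[3])
  } else {
    H <- attr(image, "H"); W <- attr(image, "W")
    x <- image
  }
  if (ncol(x) != cfg$in_channels)
    stop("expected ", cfg$in_channels, " image channels, got ", ncol(x))
  if (min(x) < 0 || max(x) > 1)
    warning("image values outside [0, 1]")
  if (H < cfg$kernel || W < cfg$kernel)
    stop("image smaller than the encoder kernel")
  k <- cfg$kernel
  cur <- conv2d(x, weights$enc1$w, weights$enc1$b, H, W, k)
  imap <- conv2d(cur, weights$enc2$w, weights$enc2$b, H, W, k)
  nf <- neuron_forward(rep(list(imap), cfg$t_steps), cfg$neuron)
  spike_train(nf$spikes, H, W)
}
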