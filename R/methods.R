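# S3 methods for fitted/initialised rgc_snn models and related objects.

#' @export
print.rgc_snn <- function(x, ...) {
  sz <- model_size(x)
  if (identical(x$kind, "unet")) {
    cat("RGC spiking segmentation network (U-type, pyramid pooling)\n")
    cat("  simulation steps:  ", x$config$t_steps, "\n", sep = "")
    cat("  contracting plan:  ",
        paste(x$config$channel_plan, collapse = " -> "), "\n", sep = "")
    cat("  expansive plan:    ",
        paste(x$config$decoder_plan, collapse = " -> "), "\n", sep = "")
    cat("  classes:           ", x$config$n_classes, "\n", sep = "")
  } else {
    cat("Rate-decoded spiking classifier (", x$config$dataset_name,
        " topology, ", x$config$neuron$mode, " neurons)\n", sep = "")
    cat("  stages: ", paste(x$config$stages, collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  parameters:        %s (%.2f MB float32)\n",
              format(sz$param_count, big.mark = ","), sz$mbytes))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained:           %d epoch(s), final train loss %.4f\n",
                nrow(x$history), last$train_loss))
  } else {
    cat("  trained:           no (freshly initialised)\n")
  }
  invisible(x)
}

#' Summary of an RGC-SNN model
#'
#' Reports the per-layer shape table, parameter totals and, when the model has
#' been fitted, the tail of the training history.
#'
#' @param object an \code{rgc_snn}.
#' @param ... unused.
#' @return an object of class \code{summary.rgc_snn}.
#' @export
summary.rgc_snn <- function(object, ...) {
  lay <- object$layout
  tab <- data.frame(
    layer = names(lay),
    kernel = vapply(lay, `[`, numeric(1), 1),
    in_ch = vapply(lay, `[`, numeric(1), 2),
    out_ch = vapply(lay, `[`, numeric(1), 3),
    row.names = NULL)
  tab$params <- tab$kernel^2 * tab$in_ch * tab$out_ch + tab$out_ch
  extra <- setdiff(names(object$params),
                   c(paste0(tab$layer, ".w"), paste0(tab$layer, ".b")))
  if (length(extra) > 0) {
    fc <- data.frame(layer = extra, kernel = NA, in_ch = NA, out_ch = NA,
                     params = vapply(object$params[extra], length, numeric(1)))
    tab <- rbind(tab, fc)
  }
  structure(list(kind = object$kind, layers = tab, size = model_size(object),
                 history = object$history, config = object$config),
            class = "summary.rgc_snn")
}

#' @export
print.summary.rgc_snn <- function(x, ...) {
  cat("Layer table (", x$kind, "):\n", sep = "")
  print(x$layers, row.names = FALSE)
  cat(sprintf("\nTotal: %s parameters, %d bytes (%.2f MB float32)\n",
              format(x$size$param_count, big.mark = ","),
              x$size$bytes, x$size$mbytes))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat("\nTraining history (last epochs):\n")
    print(utils::tail(x$history, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Model coefficients
#'
#' Returns the trainable parameters as a named list of weight matrices and
#' bias vectors, one pair per convolution (\code{"<layer>.w"},
#' \code{"<layer>.b"}).
#'
#' @param object an \code{rgc_snn}.
#' @param ... unused.
#' @return named list of numeric arrays.
#' @export
coef.rgc_snn <- function(object, ...) object$params

#' Predict segmentation masks or class evidence
#'
#' Runs the full spiking forward pass over all simulation steps and decodes
#' the time-accumulated class evidence.
#'
#' @param object a segmentation \code{rgc_snn} (for classifiers the return is
#'   a 0-based label, or softmax probabilities with \code{type = "prob"}).
#' @param newdata one image (H x W x 3 array or \code{\link{labeled_image}})
#'   or a list of such; H and W must be divisible by 16.
#' @param type \code{"mask"} for the 0-based class-index matrix,
#'   \code{"counts"} for the accumulated per-class evidence
#'   (\code{segmentation_output}), or \code{"prob"} for the softmax of the
#'   evidence ((H*W) x n_classes matrix).
#' @param ... unused.
#' @return see \code{type}; a list of results when \code{newdata} is a list.
#' @export
predict.rgc_snn <- function(object, newdata,
                            type = c("mask", "counts", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !inherits(newdata, "labeled_image") &&
      is.null(dim(newdata)))
    return(lapply(newdata, function(it) predict(object, it, type = type)))
  img <- if (inherits(newdata, "labeled_image")) newdata$image else newdata
  if (identical(object$kind, "classifier")) {
    x <- if (length(dim(img)) == 3) .image_matrix(img) else img
    ev <- classifier_forward(object, x)$evidence
    if (type == "prob") {
      e <- exp(ev - max(ev))
      return(e / sum(e))
    }
    return(which.max(ev) - 1L)
  }
  stopifnot(length(dim(img)) == 3)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  fwd <- unet_forward(object, .image_matrix(img), H, W)
  out <- decode_prediction(fwd$logits, H, W)
  switch(type,
    mask = out$mask,
    counts = out,
    prob = {
      m <- fwd$evidence - apply(fwd$evidence, 1, max)
      e <- exp(m)
      e / rowSums(e)
    })
}

#' Plot training history or parameter distribution
#'
#' For a fitted model, plots the train (and test, when available) loss curves
#' against the epoch; for an unfitted model, plots the per-layer parameter
#' counts.
#'
#' @param x an \code{rgc_snn}.
#' @param ... passed to the underlying base plotting call.
#' @return \code{x}, invisibly.
#' @export
plot.rgc_snn <- function(x, ...) {
  h <- x$history
  if (!is.null(h) && nrow(h) > 0) {
    rng <- range(c(h$train_loss, h$test_loss), na.rm = TRUE)
    graphics::plot(h$epoch, h$train_loss, type = "l", col = "black",
                   xlab = "epoch", ylab = "loss", ylim = rng,
                   main = "Training history", ...)
    if (any(!is.na(h$test_loss))) {
      graphics::lines(h$epoch, h$test_loss, col = "red")
      graphics::legend("topright", legend = c("train", "test"),
                       col = c("black", "red"), lty = 1, bty = "n")
    }
  } else {
    cnt <- vapply(x$layout, function(s) s[1]^2 * s[2] * s[3] + s[3], numeric(1))
    graphics::barplot(cnt, names.arg = names(x$layout), las = 2,
                      ylab = "parameters", main = "Parameters per layer", ...)
  }
  invisible(x)
}

#' @export
print.segmentation_output <- function(x, ...) {
  d <- dim(x$mask)
  cat("Segmentation output (", d[1], " x ", d[2], " pixels, ",
      ncol(x$spike_counts), " classes)\n", sep = "")
  tabs <- table(factor(x$mask, levels = 0:(ncol(x$spike_counts) - 1)))
  cat("  predicted pixels per class:",
      paste(sprintf("%s: %d", names(tabs), as.integer(tabs)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.segmentation_output <- function(x, ...) {
  graphics::image(t(x$mask)[, nrow(x$mask):1], col = c("firebrick", "wheat"),
                  axes = FALSE, main = "Predicted mask", ...)
  invisible(x)
}
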