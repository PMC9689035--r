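#' Training configuration
#'
#' Settings of the surrogate-gradient training loop: shuffled mini-batches,
#' cross-entropy on the softmax of the time-accumulated class evidence, and
#' Adam updates. All stochasticity (weight initialisation, shuffling, online
#' jitter draws) flows from \code{seed}.
#'
#' @param lr Adam learning rate (> 0); 1e-4 matches the published setup.
#' @param epochs number of epochs (>= 1); 1000 at full scale, far fewer at
#'   desk scale.
#' @param batch_size mini-batch size.
#' @param seed integer seed governing all randomness of the run.
#' @param shuffle reshuffle the training data every epoch.
#' @param loss loss name; only \code{"cross_entropy"} is implemented.
#' @param online_jitter re-draw one colour-jitter transform per image per
#'   batch during training (in addition to any offline augmentation).
#' @param stop_pa optional early-stopping target: stop once the test pixel
#'   accuracy reaches this value.
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @param verbose print per-epoch progress.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(lr = 1e-4, epochs = 1000, batch_size = 4, seed = 1,
                         shuffle = TRUE, loss = "cross_entropy",
                         online_jitter = TRUE, stop_pa = NULL,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         verbose = FALSE) {
  stopifnot(lr >= 0, epochs >= 1, batch_size >= 1,
            identical(loss, "cross_entropy"))
  structure(list(lr = lr, epochs = epochs, batch_size = batch_size,
                 seed = seed, shuffle = shuffle, loss = loss,
                 online_jitter = online_jitter, stop_pa = stop_pa,
                 beta1 = beta1, beta2 = beta2, eps = eps, verbose = verbose),
            class = "train_config")
}

#' Cross-entropy loss on class evidence
#'
#' Applies a softmax over the class axis of the time-accumulated evidence and
#' returns the mean over pixels of the negative log-probability of the true
#' class.
#'
#' @param pred (H*W) x n_classes evidence matrix (or an n_classes x H x W
#'   array).
#' @param label integer matrix/vector of true classes in
#'   \code{0:(n_classes-1)}.
#' @return scalar loss.
#' @export
ce_loss <- function(pred, label) {
  if (is.array(pred) && length(dim(pred)) == 3) {
    d <- dim(pred)
    pred <- matrix(aperm(pred, c(2, 3, 1)), d[2] * d[3], d[1])
  }
  .ce_loss_grad(pred, as.integer(label))$loss
}

# Loss and gradient w.r.t. the evidence, in one pass.
.ce_loss_grad <- function(evidence, label) {
  n <- ncol(evidence)
  label <- as.integer(label)
  if (any(label < 0L | label >= n)) stop("label outside the class range")
  m <- evidence - apply(evidence, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  npix <- nrow(evidence)
  idx <- cbind(seq_len(npix), label + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / npix, prob = p)
}

# -- Adam ---------------------------------------------------------------------

adam_state <- function() list(m = list(), v = list(), t = 0)

adam_step <- function(params, grads, state, control) {
  state$t <- state$t + 1
  b1 <- control$beta1; b2 <- control$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      control$lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + control$eps)
  }
  list(params = params, state = state)
}

# -- fitting ------------------------------------------------------------------

.image_matrix <- function(image) {
  d <- dim(image)
  matrix(image, d[1] * d[2], d[3])
}

.sum_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

.scale_grads <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

#' Fit the RGC spiking segmentation network
#'
#' Builds a U-type RGC-SNN from \code{config} and trains it with
#' surrogate-gradient backpropagation-through-time: per mini-batch, a forward
#' pass over all simulation steps, cross-entropy on the softmax of the
#' time-summed class evidence, a backward pass substituting the rectangular
#' surrogate for the spike derivative, and an Adam update. Training data are
#' reshuffled every epoch.
#'
#' @param train list of labelled images (\code{\link{labeled_image}}); all
#'   images must share one size divisible by 16.
#' @param test optional held-out list evaluated every epoch (loss and pixel
#'   accuracy recorded in the history; enables \code{stop_pa}).
#' @param config a \code{\link{network_config}}.
#' @param control a \code{\link{train_config}}.
#' @return A fitted model of class \code{rgc_snn} with a \code{history} data
#'   frame (epoch, train_loss, test_loss, test_pa).
#' @export
fit_rgcsnn <- function(train, test = NULL, config = network_config(),
                       control = train_config()) {
  stopifnot(length(train) >= 1)
  set.seed(control$seed)
  model <- build_rgc_unet(config)
  d <- dim(train[[1]]$image)
  H <- d[1]; W <- d[2]
  xs <- lapply(train, function(it) .image_matrix(it$image))
  ys <- lapply(train, function(it) as.integer(it$mask))
  test_xs <- lapply(test, function(it) .image_matrix(it$image))
  test_ys <- lapply(test, function(it) as.integer(it$mask))

  st <- adam_state()
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     test_loss = numeric(), test_pa = numeric())
  ntr <- length(train)
  for (ep in seq_len(control$epochs)) {
    ord <- if (control$shuffle) sample.int(ntr) else seq_len(ntr)
    ep_loss <- 0
    nbatch <- 0
    for (start in seq(1, ntr, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1, ntr)]
      gacc <- NULL
      bloss <- 0
      for (i in idx) {
        x <- xs[[i]]
        if (control$online_jitter) x <- .jitter_matrix(x, H, W)
        fwd <- unet_forward(model, x, H, W)
        lg <- .ce_loss_grad(fwd$evidence, ys[[i]])
        if (!is.finite(lg$loss))
          stop("non-finite loss at epoch ", ep, ", sample ", i,
               " (evidence range ",
               paste(signif(range(fwd$evidence), 4), collapse = ".."), ")")
        bloss <- bloss + lg$loss
        gacc <- .sum_grads(gacc, unet_backward(model, fwd, lg$grad))
      }
      gacc <- .scale_grads(gacc, 1 / length(idx))
      if (control$lr > 0) {
        upd <- adam_step(model$params, gacc, st, control)
        model$params <- upd$params
        st <- upd$state
      }
      ep_loss <- ep_loss + bloss / length(idx)
      nbatch <- nbatch + 1
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / nbatch,
                      test_loss = NA_real_, test_pa = NA_real_)
    if (length(test_xs) > 0) {
      tl <- 0; correct <- 0; total <- 0
      for (j in seq_along(test_xs)) {
        fwd <- unet_forward(model, test_xs[[j]], H, W)
        lg <- .ce_loss_grad(fwd$evidence, test_ys[[j]])
        tl <- tl + lg$loss
        pred <- max.col(fwd$evidence, ties.method = "first") - 1L
        correct <- correct + sum(pred == test_ys[[j]])
        total <- total + length(pred)
      }
      row$test_loss <- tl / length(test_xs)
      row$test_pa <- correct / total
    }
    hist <- rbind(hist, row)
    if (control$verbose)
      message(sprintf("epoch %d: train loss %.4f, test PA %s", ep,
                      row$train_loss,
                      if (is.na(row$test_pa)) "-" else sprintf("%.4f", row$test_pa)))
    if (!is.null(control$stop_pa) && !is.na(row$test_pa) &&
        row$test_pa >= control$stop_pa) break
  }
  model$history <- hist
  model$control <- control
  model
}

#' Fit a rate-decoded spiking classifier
#'
#' Trains a benchmark classifier (see \code{\link{build_classifier}}) with the
#' same surrogate-gradient loop: cross-entropy on the softmax of the
#' time-summed class evidence, Adam, shuffled mini-batches.
#'
#' @param model an \code{rgc_snn} classifier from
#'   \code{\link{build_classifier}}.
#' @param train list of \code{list(image, label)} with 0-based integer labels;
#'   images as S x S x C arrays or (S*S) x C matrices.
#' @param test optional held-out list; accuracy recorded per epoch.
#' @param control a \code{\link{train_config}}.
#' @return the fitted classifier with a \code{history} data frame.
#' @export
fit_classifier <- function(model, train, test = NULL,
                           control = train_config(online_jitter = FALSE)) {
  set.seed(control$seed)
  prep <- function(it) {
    x <- it$image
    if (is.array(x) && length(dim(x)) == 3) x <- .image_matrix(x)
    if (is.null(dim(x))) x <- matrix(x, ncol = model$config$in_channels)
    x
  }
  xs <- lapply(train, prep)
  ys <- vapply(train, function(it) as.integer(it$label), integer(1))
  test_xs <- lapply(test, prep)
  test_ys <- vapply(test, function(it) as.integer(it$label), integer(1))

  st <- adam_state()
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     test_acc = numeric())
  ntr <- length(train)
  for (ep in seq_len(control$epochs)) {
    ord <- if (control$shuffle) sample.int(ntr) else seq_len(ntr)
    ep_loss <- 0
    nbatch <- 0
    for (start in seq(1, ntr, by = control$batch_size)) {
      idx <- ord[start:min(start + control$batch_size - 1, ntr)]
      gacc <- NULL
      bloss <- 0
      for (i in idx) {
        fwd <- classifier_forward(model, xs[[i]])
        lg <- .ce_loss_grad(matrix(fwd$evidence, 1), ys[i])
        if (!is.finite(lg$loss)) stop("non-finite loss at epoch ", ep)
        bloss <- bloss + lg$loss
        gacc <- .sum_grads(gacc, classifier_backward(model, fwd, drop(lg$grad)))
      }
      gacc <- .scale_grads(gacc, 1 / length(idx))
      if (control$lr > 0) {
        upd <- adam_step(model$params, gacc, st, control)
        model$params <- upd$params
        st <- upd$state
      }
      ep_loss <- ep_loss + bloss / length(idx)
      nbatch <- nbatch + 1
    }
    acc <- NA_real_
    if (length(test_xs) > 0) {
      hits <- vapply(seq_along(test_xs), function(j) {
        ev <- classifier_forward(model, test_xs[[j]])$evidence
        (which.max(ev) - 1L) == test_ys[j]
      }, logical(1))
      acc <- mean(hits)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nbatch,
                                   test_acc = acc))
    if (control$verbose)
      message(sprintf("epoch %d: loss %.4f acc %s", ep, ep_loss / nbatch,
                      if (is.na(acc)) "-" else sprintf("%.3f", acc)))
  }
  model$history <- hist
  model$control <- control
  model
}
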