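#' U-type RGC-SNN configuration
#'
#' Describes the full segmentation network: a trainable convolutional spike
#' encoder, a contracting path of four skip-concatenation (SC) modules each
#' followed by 2x2 average pooling, a pyramid pooling module (PPM) over the
#' bottleneck, and an expansive path that upsamples bilinearly, concatenates
#' the matching SC output, and refines with pairs of spiking convolutions.
#' The final prediction convolution accumulates real-valued class evidence per
#' time step; the class with the most accumulated evidence over the simulation
#' window is the predicted class.
#'
#' @param t_steps simulation time steps.
#' @param channel_plan widths of the contracting stages; each entry must be
#'   double its predecessor (SC concatenation doubles channels). The first
#'   entry is the encoder output width.
#' @param sc_kernel kernel size of the SC convolutions.
#' @param ppm_bins adaptive pooling target sizes of the PPM branches.
#' @param ppm_branch_channels width of each PPM branch after its 1x1
#'   convolution; defaults to a quarter of the bottleneck width so the
#'   concatenation doubles the bottleneck channels.
#' @param decoder_plan widths of the four expansive stages (deepest first);
#'   defaults to the mirrored contracting plan scaled by \code{decoder_scale}.
#' @param decoder_scale fixed width calibration constant of the expansive path
#'   (29/24), chosen so the default network stores about 16.6 MB of float32
#'   parameters.
#' @param n_classes number of output classes.
#' @param pred_kernel kernel size of the final prediction convolution.
#' @param encoder an \code{\link{encoder_config}}; built from the plan when
#'   omitted.
#' @param neuron a \code{\link{neuron_params}} shared by all spiking layers.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(t_steps = 8,
                           channel_plan = c(24, 48, 96, 192, 384),
                           sc_kernel = 3,
                           ppm_bins = c(1, 2, 3, 6),
                           ppm_branch_channels = NULL,
                           decoder_plan = NULL,
                           decoder_scale = 29 / 24,
                           n_classes = 2,
                           pred_kernel = 3,
                           encoder = NULL,
                           neuron = neuron_params()) {
  stopifnot(length(channel_plan) == 5, t_steps >= 1, sc_kernel %% 2 == 1,
            n_classes >= 2, pred_kernel %% 2 == 1)
  if (!all(channel_plan[-1] == 2 * channel_plan[-5]))
    stop("each stage width must be double its predecessor")
  if (is.null(ppm_branch_channels))
    ppm_branch_channels <- channel_plan[5] %/% 4
  if (is.null(decoder_plan))
    decoder_plan <- round(rev(channel_plan[1:4]) * decoder_scale)
  stopifnot(length(decoder_plan) == 4)
  if (is.null(encoder))
    encoder <- encoder_config(out_channels = channel_plan[1],
                              t_steps = t_steps, neuron = neuron)
  if (encoder$out_channels != channel_plan[1])
    stop("encoder output width must equal the first contracting width")
  structure(list(t_steps = t_steps, channel_plan = channel_plan,
                 sc_kernel = sc_kernel, ppm_bins = ppm_bins,
                 ppm_branch_channels = ppm_branch_channels,
                 decoder_plan = decoder_plan, n_classes = n_classes,
                 pred_kernel = pred_kernel, encoder = encoder,
                 neuron = neuron),
            class = "network_config")
}

# Shapes (kernel, in-channels, out-channels) of every trainable convolution,
# in canonical build order; the fully connected "out" head of classifiers is
# handled separately.
unet_layout <- function(cfg) {
  plan <- cfg$channel_plan
  dp <- cfg$decoder_plan
  ke <- cfg$encoder$kernel
  k3 <- cfg$sc_kernel
  lay <- list(
    enc1 = c(ke, cfg$encoder$in_channels, plan[1]),
    enc2 = c(ke, plan[1], plan[1])
  )
  for (i in 1:4) {
    lay[[paste0("sc", i, ".c1")]] <- c(k3, plan[i], plan[i])
    lay[[paste0("sc", i, ".c2")]] <- c(k3, plan[i], plan[i])
  }
  for (b in seq_along(cfg$ppm_bins))
    lay[[paste0("ppm.b", b)]] <- c(1, plan[5], cfg$ppm_branch_channels)
  lay[["ppm.comp"]] <- c(1, plan[5] + length(cfg$ppm_bins) * cfg$ppm_branch_channels,
                         plan[5])
  up_c <- plan[5]
  for (j in 1:4) {
    skip_c <- plan[6 - j]
    lay[[paste0("dec", j, ".c1")]] <- c(k3, up_c + skip_c, dp[j])
    lay[[paste0("dec", j, ".c2")]] <- c(k3, dp[j], dp[j])
    up_c <- dp[j]
  }
  lay[["pred"]] <- c(cfg$pred_kernel, dp[4], cfg$n_classes)
  lay
}

#' Build an untrained RGC-SNN segmentation network
#'
#' Initialises the full parameter set (He-normal weights, zero biases) of the
#' U-type network described by \code{cfg}. Parameters are stored in a flat
#' named list (\code{"<layer>.w"} / \code{"<layer>.b"}).
#'
#' @param cfg a \code{\link{network_config}}.
#' @param seed optional seed applied before initialisation.
#' @return an untrained model of class \code{rgc_snn}.
#' @export
build_rgc_unet <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- unet_layout(cfg)
  params <- list()
  for (nm in names(lay)) {
    s <- lay[[nm]]
    cv <- init_conv(s[1], s[2], s[3])
    params[[paste0(nm, ".w")]] <- cv$w
    params[[paste0(nm, ".b")]] <- cv$b
  }
  structure(list(config = cfg, params = params, layout = lay, kind = "unet"),
            class = "rgc_snn")
}

#' Trainable parameter count and storage size
#'
#' Sums all trainable weights and biases of a network and reports the float32
#' storage footprint.
#'
#' @param x a \code{\link{network_config}} or a fitted/initialised
#'   \code{rgc_snn} model.
#' @return list with \code{param_count}, \code{bytes} (count x 4),
#'   \code{mbytes} (decimal MB) and \code{mib} (binary MiB).
#' @export
model_size <- function(x) {
  if (inherits(x, "rgc_snn")) {
    n <- sum(vapply(x$params, length, numeric(1)))
  } else if (inherits(x, "network_config")) {
    lay <- unet_layout(x)
    n <- sum(vapply(lay, function(s) s[1]^2 * s[2] * s[3] + s[3], numeric(1)))
  } else stop("unsupported object")
  bytes <- 4 * n
  list(param_count = n, bytes = bytes, mbytes = bytes / 1e6, mib = bytes / 2^20)
}

# -- forward ------------------------------------------------------------------

conv_steps <- function(sp, P, nm, H, W, k) {
  w <- P[[paste0(nm, ".w")]]
  b <- P[[paste0(nm, ".b")]]
  lapply(sp, function(s) conv2d(s, w, b, H, W, k))
}

#' Skip-concatenation module forward pass
#'
#' Applies two spiking convolution layers to a binary spike train and
#' concatenates the result with the untouched input along the channel axis,
#' doubling the channel count; the last \code{c} channels of the output equal
#' the input exactly.
#'
#' @param sp list of T binary (H*W) x c matrices.
#' @param conv1,conv2 convolution parameters (\code{list(w, b)}).
#' @param H,W spatial size; \code{k} kernel size.
#' @param neuron a \code{\link{neuron_params}}.
#' @param relaxed internal: use the differentiable spike relaxation.
#' @return list with \code{out} (list of T (H*W) x 2c matrices) and the neuron
#'   caches.
#' @export
sc_forward <- function(sp, conv1, conv2, H, W, k = 3, neuron = neuron_params(),
                       relaxed = FALSE) {
  a <- lapply(sp, function(s) conv2d(s, conv1$w, conv1$b, H, W, k))
  n1 <- neuron_forward(a, neuron, relaxed)
  b <- lapply(n1$spikes, function(s) conv2d(s, conv2$w, conv2$b, H, W, k))
  n2 <- neuron_forward(b, neuron, relaxed)
  out <- mapply(cbind, n2$spikes, sp, SIMPLIFY = FALSE)
  list(out = out, n1 = n1, n2 = n2)
}

#' Full segmentation network forward pass
#'
#' Runs encoder, contracting path, pyramid pooling and expansive path over all
#' simulation steps.
#'
#' @param model an \code{rgc_snn} from \code{\link{build_rgc_unet}}.
#' @param x input image as an (H*W) x in_channels matrix (column-major
#'   pixels).
#' @param H,W spatial size; both divisible by 16.
#' @param relaxed substitute the piecewise-linear spike relaxation (gradient
#'   verification only).
#' @return list with \code{evidence} ((H*W) x n_classes time-summed class
#'   evidence), \code{logits} (list of per-step evidence matrices) and the
#'   caches consumed by \code{\link{unet_backward}}.
#' @export
unet_forward <- function(model, x, H, W, relaxed = FALSE) {
  cfg <- model$config
  P <- model$params
  stopifnot(H %% 16 == 0, W %% 16 == 0)
  tt <- cfg$t_steps
  np <- cfg$neuron
  k3 <- cfg$sc_kernel
  ke <- cfg$encoder$kernel
  plan <- cfg$channel_plan

  cur <- conv2d(x, P[["enc1.w"]], P[["enc1.b"]], H, W, ke)
  imap <- conv2d(cur, P[["enc2.w"]], P[["enc2.b"]], H, W, ke)
  nenc <- neuron_forward(rep(list(imap), tt), cfg$encoder$neuron, relaxed)
  sp <- nenc$spikes

  h <- H; w <- W
  stages <- vector("list", 4)
  skips <- vector("list", 4)
  for (i in 1:4) {
    nm <- paste0("sc", i)
    sc <- sc_forward(sp,
                     list(w = P[[paste0(nm, ".c1.w")]], b = P[[paste0(nm, ".c1.b")]]),
                     list(w = P[[paste0(nm, ".c2.w")]], b = P[[paste0(nm, ".c2.b")]]),
                     h, w, k3, np, relaxed)
    stages[[i]] <- list(in_sp = sp, n1 = sc$n1, n2 = sc$n2, H = h, W = w)
    skips[[i]] <- sc$out
    sp <- lapply(sc$out, avgpool2, H = h, W = w)
    h <- h %/% 2L; w <- w %/% 2L
  }

  # pyramid pooling over the bottleneck
  bins <- cfg$ppm_bins
  pb <- vector("list", tt)       # pooled branch inputs, per step per branch
  concat <- vector("list", tt)
  for (t in seq_len(tt)) {
    ups <- vector("list", length(bins))
    pb[[t]] <- vector("list", length(bins))
    for (bi in seq_along(bins)) {
      b <- bins[bi]
      Pm <- adaptive_pool_matrix(h, w, b)
      pooled <- Pm %*% sp[[t]]
      pb[[t]][[bi]] <- pooled
      pc <- pooled %*% P[[paste0("ppm.b", bi, ".w")]] +
        rep(P[[paste0("ppm.b", bi, ".b")]], each = b * b)
      ups[[bi]] <- resize_bilinear(pc, b, b, h, w)
    }
    concat[[t]] <- do.call(cbind, c(list(sp[[t]]), ups))
  }
  comp <- lapply(concat, function(m)
    m %*% P[["ppm.comp.w"]] + rep(P[["ppm.comp.b"]], each = h * w))
  nppm <- neuron_forward(comp, np, relaxed)
  ppm_cache <- list(in_sp = sp, pb = pb, concat = concat, n = nppm, H = h, W = w)
  x_sp <- nppm$spikes

  # expansive path
  dec <- vector("list", 4)
  for (j in 1:4) {
    st <- stages[[5 - j]]
    sh <- st$H; sw <- st$W
    up <- lapply(x_sp, resize_bilinear, H = h, W = w, Hout = sh, Wout = sw)
    up_c <- ncol(up[[1]])
    cat_t <- mapply(cbind, up, skips[[5 - j]], SIMPLIFY = FALSE)
    nm <- paste0("dec", j)
    a <- conv_steps(cat_t, P, paste0(nm, ".c1"), sh, sw, k3)
    n1 <- neuron_forward(a, np, relaxed)
    b2 <- conv_steps(n1$spikes, P, paste0(nm, ".c2"), sh, sw, k3)
    n2 <- neuron_forward(b2, np, relaxed)
    dec[[j]] <- list(cat = cat_t, n1 = n1, n2 = n2, H = sh, W = sw,
                     up_c = up_c, prev_H = h, prev_W = w)
    x_sp <- n2$spikes
    h <- sh; w <- sw
  }

  logits <- conv_steps(x_sp, P, "pred", H, W, cfg$pred_kernel)
  evidence <- Reduce(`+`, logits)
  list(evidence = evidence, logits = logits,
       cache = list(x = x, cur = cur, nenc = nenc, stages = stages,
                    skips = skips, ppm = ppm_cache, dec = dec,
                    H = H, W = W))
}

# -- backward -----------------------------------------------------------------

# Accumulating gradient store keyed like the parameter list.
.grad_store <- function() {
  env <- new.env(parent = emptyenv())
  list(
    add = function(nm, gw, gb) {
      key_w <- paste0(nm, ".w"); key_b <- paste0(nm, ".b")
      if (is.null(env[[key_w]])) { env[[key_w]] <- gw; env[[key_b]] <- gb }
      else { env[[key_w]] <- env[[key_w]] + gw; env[[key_b]] <- env[[key_b]] + gb }
    },
    collect = function() as.list(env)
  )
}

# Backward through a conv applied per time step. Returns grads w.r.t. inputs.
conv_steps_backward <- function(gs, inputs, P, G, nm, H, W, k) {
  w <- P[[paste0(nm, ".w")]]
  wflip <- .flip_weight(w, k)
  out <- vector("list", length(gs))
  for (t in seq_along(gs)) {
    bk <- conv2d_backward(inputs[[t]], gs[[t]], w, H, W, k, wflip)
    G$add(nm, bk$w, bk$b)
    out[[t]] <- bk$x
  }
  out
}

#' Full segmentation network backward pass
#'
#' Backpropagation through time with the rectangular surrogate gradient at
#' every spiking nonlinearity.
#'
#' @param model the \code{rgc_snn} used for the forward pass.
#' @param fwd the list returned by \code{\link{unet_forward}}.
#' @param g_evidence gradient of the loss w.r.t. the time-accumulated class
#'   evidence ((H*W) x n_classes).
#' @return flat named list of parameter gradients matching
#'   \code{model$params}.
#' @export
unet_backward <- function(model, fwd, g_evidence) {
  cfg <- model$config
  P <- model$params
  ca <- fwd$cache
  tt <- cfg$t_steps
  k3 <- cfg$sc_kernel
  plan <- cfg$channel_plan
  G <- .grad_store()

  # prediction head: evidence = sum_t conv(spikes_t)
  g_sp <- conv_steps_backward(rep(list(g_evidence), tt), ca$dec[[4]]$n2$spikes,
                              P, G, "pred", ca$H, ca$W, cfg$pred_kernel)

  # expansive path (reverse order)
  g_skips <- vector("list", 4)
  for (j in 4:1) {
    dc <- ca$dec[[j]]
    nm <- paste0("dec", j)
    g_b <- neuron_backward(dc$n2, g_sp)
    g_n1 <- conv_steps_backward(g_b, dc$n1$spikes, P, G, paste0(nm, ".c2"),
                                dc$H, dc$W, k3)
    g_a <- neuron_backward(dc$n1, g_n1)
    g_cat <- conv_steps_backward(g_a, dc$cat, P, G, paste0(nm, ".c1"),
                                 dc$H, dc$W, k3)
    up_c <- dc$up_c
    skip_cols <- (up_c + 1):ncol(g_cat[[1]])
    g_skips[[5 - j]] <- lapply(g_cat, function(g) g[, skip_cols, drop = FALSE])
    g_sp <- lapply(g_cat, function(g)
      resize_bilinear_grad(g[, seq_len(up_c), drop = FALSE],
                           dc$prev_H, dc$prev_W, dc$H, dc$W))
  }

  # pyramid pooling
  pc <- ca$ppm
  h <- pc$H; w <- pc$W
  g_comp <- neuron_backward(pc$n, g_sp)
  wcomp <- P[["ppm.comp.w"]]
  bins <- cfg$ppm_bins
  g_bottom <- vector("list", tt)
  for (t in seq_len(tt)) {
    G$add("ppm.comp", crossprod(pc$concat[[t]], g_comp[[t]]), colSums(g_comp[[t]]))
    g_concat <- g_comp[[t]] %*% t(wcomp)
    cin <- plan[5]
    g_direct <- g_concat[, seq_len(cin), drop = FALSE]
    off <- cin
    for (bi in seq_along(bins)) {
      b <- bins[bi]
      bc <- cfg$ppm_branch_channels
      g_up <- g_concat[, off + seq_len(bc), drop = FALSE]
      off <- off + bc
      g_pc <- resize_bilinear_grad(g_up, b, b, h, w)
      nm <- paste0("ppm.b", bi)
      G$add(nm, crossprod(pc$pb[[t]][[bi]], g_pc), colSums(g_pc))
      g_pb <- g_pc %*% t(P[[paste0(nm, ".w")]])
      g_direct <- g_direct + crossprod(adaptive_pool_matrix(h, w, b), g_pb)
    }
    g_bottom[[t]] <- g_direct
  }
  g_sp <- g_bottom

  # contracting path (reverse order)
  for (i in 4:1) {
    st <- ca$stages[[i]]
    nm <- paste0("sc", i)
    c_i <- plan[i]
    g_out <- vector("list", tt)
    for (t in seq_len(tt)) {
      g_out[[t]] <- avgpool2_grad(g_sp[[t]], st$H, st$W) + g_skips[[i]][[t]]
    }
    g_b2 <- lapply(g_out, function(g) g[, seq_len(c_i), drop = FALSE])
    g_pass <- lapply(g_out, function(g) g[, c_i + seq_len(c_i), drop = FALSE])
    g_cb <- neuron_backward(st$n2, g_b2)
    g_n1 <- conv_steps_backward(g_cb, st$n1$spikes, P, G, paste0(nm, ".c2"),
                                st$H, st$W, k3)
    g_ca <- neuron_backward(st$n1, g_n1)
    g_in <- conv_steps_backward(g_ca, st$in_sp, P, G, paste0(nm, ".c1"),
                                st$H, st$W, k3)
    g_sp <- mapply(`+`, g_in, g_pass, SIMPLIFY = FALSE)
  }

  # encoder: the same current map is injected at every step
  g_imap_steps <- neuron_backward(ca$nenc, g_sp)
  g_imap <- Reduce(`+`, g_imap_steps)
  ke <- cfg$encoder$kernel
  gw2 <- conv2d_grad_weight(ca$cur, g_imap, ca$H, ca$W, ke)
  G$add("enc2", gw2$w, gw2$b)
  g_cur <- conv2d_grad_input(g_imap, P[["enc2.w"]], ca$H, ca$W, ke)
  gw1 <- conv2d_grad_weight(ca$x, g_cur, ca$H, ca$W, ke)
  G$add("enc1", gw1$w, gw1$b)

  G$collect()
}

#' Rate decoding of the prediction maps
#'
#' Sums the per-step class evidence (discharges for spiking heads) over the
#' simulation window and assigns each pixel the class with the largest total;
#' ties break toward the lowest class index.
#'
#' @param logits either a list of T (H*W) x n_classes matrices or a
#'   \code{[T, n_classes, H, W]} array.
#' @param H,W spatial size (required for the list form).
#' @return list of class \code{segmentation_output} with \code{spike_counts}
#'   ((H*W) x n_classes totals) and \code{mask} (H x W matrix of 0-based class
#'   indices).
#' @export
decode_prediction <- function(logits, H = NULL, W = NULL) {
  if (is.array(logits) && length(dim(logits)) == 4) {
    d <- dim(logits)
    H <- d[3]; W <- d[4]
    lst <- lapply(seq_len(d[1]), function(t) {
      m <- matrix(aperm(logits[t, , , , drop = FALSE][1, , , ], c(2, 3, 1)), H * W, d[2])
      m
    })
    logits <- lst
  }
  counts <- Reduce(`+`, logits)
  # ties break toward the lowest index: strict comparison against the running max
  idx <- rep(0L, nrow(counts))
  best <- counts[, 1]
  for (j in seq_len(ncol(counts))[-1]) {
    better <- counts[, j] > best
    idx[better] <- j - 1L
    best[better] <- counts[better, j]
  }
  structure(list(spike_counts = counts,
                 counts_array = aperm(array(counts, c(H, W, ncol(counts))),
                                      c(3, 1, 2)),
                 mask = matrix(idx, H, W)),
            class = "segmentation_output")
}

# -- Table-1 classifier builders ---------------------------------------------

.classifier_stages <- list(
  mnist = c("encode", "rgc", "ap", "rgc", "ap", "rgc", "rgc", "out"),
  n_mnist = c("encode", "rgc", "rgc", "out"),
  dvs128 = c("encode", "ap", "rgc", "rgc", "ap", "rgc", "ap", "rgc", "out")
)

#' Build a rate-decoded spiking classifier
#'
#' Constructs the benchmark classifier topologies (MNIST / N-MNIST / DVS-128
#' layouts) with either RGC or LIF neurons: a convolutional spike encoder
#' followed by spiking convolution layers, average pooling, and a fully
#' connected rate-decoded head.
#'
#' @param dataset_name one of \code{"mnist"}, \code{"n_mnist"}, \code{"dvs128"}.
#' @param neuron_mode \code{"rgc"} or \code{"lif"}.
#' @param input_size square input side (must be divisible by 2 per pooling
#'   stage).
#' @param in_channels input channels.
#' @param width channel width of all convolution stages.
#' @param n_classes number of classes.
#' @param t_steps simulation steps.
#' @param kernel convolution kernel size.
#' @param neuron base \code{\link{neuron_params}}; its \code{mode} is set from
#'   \code{neuron_mode}.
#' @param seed RNG seed for weight initialisation.
#' @return An object of class \code{rgc_snn} (kind \code{"classifier"}).
#' @export
build_classifier <- function(dataset_name = c("mnist", "n_mnist", "dvs128"),
                             neuron_mode = c("rgc", "lif"),
                             input_size = 16, in_channels = 1, width = 8,
                             n_classes = 10, t_steps = 8, kernel = 3,
                             neuron = neuron_params(), seed = NULL) {
  dataset_name <- match.arg(dataset_name)
  neuron_mode <- match.arg(neuron_mode)
  neuron$mode <- neuron_mode
  if (!is.null(seed)) set.seed(seed)
  stages <- .classifier_stages[[dataset_name]]
  params <- list()
  layout <- list()
  sz <- input_size
  cin <- in_channels
  ridx <- 0
  for (s in stages) {
    if (s == "encode") {
      e1 <- init_conv(kernel, cin, width); e2 <- init_conv(kernel, width, width)
      params[["enc1.w"]] <- e1$w; params[["enc1.b"]] <- e1$b
      params[["enc2.w"]] <- e2$w; params[["enc2.b"]] <- e2$b
      layout[["enc1"]] <- c(kernel, cin, width)
      layout[["enc2"]] <- c(kernel, width, width)
      cin <- width
    } else if (s == "rgc") {
      ridx <- ridx + 1
      nm <- paste0("rgc", ridx)
      cv <- init_conv(kernel, cin, width)
      params[[paste0(nm, ".w")]] <- cv$w; params[[paste0(nm, ".b")]] <- cv$b
      layout[[nm]] <- c(kernel, cin, width)
      cin <- width
    } else if (s == "ap") {
      sz <- sz %/% 2L
    } else if (s == "out") {
      fc <- init_fc(sz * sz * cin, n_classes)
      params[["out.w"]] <- fc$w; params[["out.b"]] <- fc$b
      layout[["out"]] <- c(sz * sz * cin, n_classes)
    }
  }
  cfg <- list(stages = stages, t_steps = t_steps, kernel = kernel,
              input_size = input_size, in_channels = in_channels,
              width = width, n_classes = n_classes, neuron = neuron,
              dataset_name = dataset_name)
  structure(list(config = cfg, params = params, layout = layout,
                 kind = "classifier"),
            class = "rgc_snn")
}

# Classifier forward: x is (S*S) x in_channels. Returns class evidence vector.
classifier_forward <- function(model, x, relaxed = FALSE) {
  cfg <- model$config
  P <- model$params
  np <- cfg$neuron
  k <- cfg$kernel
  tt <- cfg$t_steps
  h <- cfg$input_size; w <- h
  caches <- list()
  sp <- NULL
  ridx <- 0
  for (s in cfg$stages) {
    if (s == "encode") {
      cur <- conv2d(x, P[["enc1.w"]], P[["enc1.b"]], h, w, k)
      imap <- conv2d(cur, P[["enc2.w"]], P[["enc2.b"]], h, w, k)
      n <- neuron_forward(rep(list(imap), tt), np, relaxed)
      caches[[length(caches) + 1]] <- list(type = "encode", cur = cur, n = n,
                                           H = h, W = w)
      sp <- n$spikes
    } else if (s == "rgc") {
      ridx <- ridx + 1
      nm <- paste0("rgc", ridx)
      a <- conv_steps(sp, P, nm, h, w, k)
      n <- neuron_forward(a, np, relaxed)
      caches[[length(caches) + 1]] <- list(type = "rgc", nm = nm, in_sp = sp,
                                           n = n, H = h, W = w)
      sp <- n$spikes
    } else if (s == "ap") {
      caches[[length(caches) + 1]] <- list(type = "ap", H = h, W = w)
      sp <- lapply(sp, avgpool2, H = h, W = w)
      h <- h %/% 2L; w <- w %/% 2L
    } else if (s == "out") {
      vsum <- Reduce(`+`, sp)
      vs <- as.vector(vsum)
      evidence <- drop(vs %*% P[["out.w"]]) + tt * P[["out.b"]]
      caches[[length(caches) + 1]] <- list(type = "out", vsum = vs,
                                           dims = dim(sp[[1]]))
      return(list(evidence = evidence, caches = caches, x = x))
    }
  }
  stop("classifier has no output stage")
}

classifier_backward <- function(model, fwd, g_evidence) {
  cfg <- model$config
  P <- model$params
  k <- cfg$kernel
  tt <- cfg$t_steps
  G <- .grad_store()
  caches <- fwd$caches
  g_sp <- NULL
  for (ci in rev(seq_along(caches))) {
    ca <- caches[[ci]]
    if (ca$type == "out") {
      G$add("out", ca$vsum %o% g_evidence, tt * g_evidence)
      g_flat <- drop(P[["out.w"]] %*% g_evidence)
      g_one <- matrix(g_flat, ca$dims[1], ca$dims[2])
      g_sp <- rep(list(g_one), tt)
    } else if (ca$type == "ap") {
      g_sp <- lapply(g_sp, avgpool2_grad, H = ca$H, W = ca$W)
    } else if (ca$type == "rgc") {
      g_a <- neuron_backward(ca$n, g_sp)
      g_sp <- conv_steps_backward(g_a, ca$in_sp, P, G, ca$nm, ca$H, ca$W, k)
    } else if (ca$type == "encode") {
      g_i <- neuron_backward(ca$n, g_sp)
      g_imap <- Reduce(`+`, g_i)
      gw2 <- conv2d_grad_weight(ca$cur, g_imap, ca$H, ca$W, k)
      G$add("enc2", gw2$w, gw2$b)
      g_cur <- conv2d_grad_input(g_imap, P[["enc2.w"]], ca$H, ca$W, k)
      gw1 <- conv2d_grad_weight(fwd$x, g_cur, ca$H, ca$W, k)
      G$add("enc1", gw1$w, gw1$b)
    }
  }
  G$collect()
}

# -- forward-only module surfaces (inspection / testing) ----------------------

#' Contracting path forward pass
#'
#' Runs the four SC + average-pooling stages on an encoded spike train and
#' returns the bottleneck train (1/16 resolution) together with the four
#' pre-pooling SC outputs used as skip connections.
#'
#' @param model an \code{rgc_snn} segmentation model.
#' @param train a \code{\link{spike_train}} with the encoder's channel count.
#' @param relaxed internal: use the differentiable spike relaxation.
#' @return list with \code{bottleneck} (a \code{spike_train}) and \code{skips}
#'   (list of 4 \code{spike_train}s at resolutions H, H/2, H/4, H/8).
#' @export
contracting_forward <- function(model, train, relaxed = FALSE) {
  cfg <- model$config
  P <- model$params
  if (train$H %% 16 != 0 || train$W %% 16 != 0)
    stop("spatial size must be divisible by 16")
  sp <- train$values
  h <- train$H; w <- train$W
  skips <- vector("list", 4)
  for (i in 1:4) {
    nm <- paste0("sc", i)
    sc <- sc_forward(sp,
                     list(w = P[[paste0(nm, ".c1.w")]], b = P[[paste0(nm, ".c1.b")]]),
                     list(w = P[[paste0(nm, ".c2.w")]], b = P[[paste0(nm, ".c2.b")]]),
                     h, w, cfg$sc_kernel, cfg$neuron, relaxed)
    # from stage 2 on the concatenated input half holds pooled (fractional)
    # values, so bypass the strict binary constructor
    skips[[i]] <- structure(list(values = sc$out, t_steps = length(sc$out),
                                 H = h, W = w, C = ncol(sc$out[[1]])),
                            class = "spike_train")
    sp <- lapply(sc$out, avgpool2, H = h, W = w)
    h <- h %/% 2L; w <- w %/% 2L
  }
  list(bottleneck = structure(list(values = sp, t_steps = length(sp), H = h,
                                   W = w, C = ncol(sp[[1]])),
                              class = "spike_train"),
       skips = skips)
}

#' Pyramid pooling module forward pass
#'
#' Per branch: adaptive average pooling to the bin size, a 1x1 convolution,
#' and bilinear upsampling back to the input size; the branches are
#' concatenated with the input (enlarging the channel count to input +
#' bins x branch width), compressed by a 1x1 convolution back to the input
#' width, and passed through a spiking layer.
#'
#' @inheritParams contracting_forward
#' @param train the bottleneck \code{\link{spike_train}} (or any list-of-steps
#'   input with matching channels).
#' @return the composite \code{spike_train}; attribute
#'   \code{"concat_channels"} records the pre-compression channel count.
#' @export
ppm_forward <- function(model, train, relaxed = FALSE) {
  cfg <- model$config
  P <- model$params
  sp <- train$values
  h <- train$H; w <- train$W
  bins <- cfg$ppm_bins
  concat_c <- NULL
  comp <- vector("list", length(sp))
  for (t in seq_along(sp)) {
    ups <- vector("list", length(bins))
    for (bi in seq_along(bins)) {
      b <- bins[bi]
      pooled <- adaptive_pool_matrix(h, w, b) %*% sp[[t]]
      pc <- pooled %*% P[[paste0("ppm.b", bi, ".w")]] +
        rep(P[[paste0("ppm.b", bi, ".b")]], each = b * b)
      ups[[bi]] <- resize_bilinear(pc, b, b, h, w)
    }
    cc <- do.call(cbind, c(list(sp[[t]]), ups))
    concat_c <- ncol(cc)
    comp[[t]] <- cc %*% P[["ppm.comp.w"]] + rep(P[["ppm.comp.b"]], each = h * w)
  }
  n <- neuron_forward(comp, cfg$neuron, relaxed)
  out <- structure(list(values = n$spikes, t_steps = length(n$spikes),
                        H = h, W = w, C = ncol(n$spikes[[1]])),
                   class = "spike_train")
  attr(out, "concat_channels") <- concat_c
  out
}

#' Expansive path forward pass
#'
#' Four stages of bilinear x2 upsampling, concatenation with the matching SC
#' skip, and two spiking convolutions, followed by the real-valued prediction
#' convolution accumulated per time step.
#'
#' @inheritParams contracting_forward
#' @param bottleneck the PPM output \code{\link{spike_train}}.
#' @param skips list of 4 skip \code{spike_train}s from
#'   \code{\link{contracting_forward}}.
#' @return list with \code{logits} (list of T (H*W) x n_classes matrices),
#'   \code{evidence}, \code{H}, \code{W}.
#' @export
expansive_forward <- function(model, bottleneck, skips, relaxed = FALSE) {
  cfg <- model$config
  P <- model$params
  sp <- bottleneck$values
  h <- bottleneck$H; w <- bottleneck$W
  for (j in 1:4) {
    sk <- skips[[5 - j]]
    if (sk$H != 2 * h || sk$W != 2 * w)
      stop("skip resolution does not match the upsampled stage")
    up <- lapply(sp, resize_bilinear, H = h, W = w, Hout = sk$H, Wout = sk$W)
    cat_t <- mapply(cbind, up, sk$values, SIMPLIFY = FALSE)
    nm <- paste0("dec", j)
    a <- conv_steps(cat_t, P, paste0(nm, ".c1"), sk$H, sk$W, cfg$sc_kernel)
    n1 <- neuron_forward(a, cfg$neuron, relaxed)
    b2 <- conv_steps(n1$spikes, P, paste0(nm, ".c2"), sk$H, sk$W, cfg$sc_kernel)
    n2 <- neuron_forward(b2, cfg$neuron, relaxed)
    sp <- n2$spikes
    h <- sk$H; w <- sk$W
  }
  logits <- conv_steps(sp, P, "pred", h, w, cfg$pred_kernel)
  list(logits = logits, evidence = Reduce(`+`, logits), H = h, W = w)
}
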