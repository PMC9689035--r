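test_that("network_config validates and derives the decoder plan", {
  cfg <- network_config()
  expect_equal(cfg$channel_plan, c(24, 48, 96, 192, 384))
  expect_equal(cfg$ppm_branch_channels, 96)
  expect_equal(cfg$decoder_plan, c(232, 116, 58, 29))
  expect_error(network_config(channel_plan = c(24, 48, 96, 192, 383)))
  expect_error(network_config(channel_plan = c(24, 40, 96, 192, 384)))
})

test_that("layer table channel arithmetic is consistent", {
  lay <- rgcsnn:::unet_layout(network_config())
  expect_equal(lay$enc1, c(7, 3, 24))
  expect_equal(lay$enc2, c(7, 24, 24))
  for (i in 1:4) {
    w <- c(24, 48, 96, 192)[i]
    expect_equal(lay[[paste0("sc", i, ".c1")]], c(3, w, w))
    expect_equal(lay[[paste0("sc", i, ".c2")]], c(3, w, w))
  }
  expect_equal(lay$ppm.b1, c(1, 384, 96))
  expect_equal(lay$ppm.comp, c(1, 768, 384))  # 384 + 4 * 96 concatenated
  # the skip from stage 4 carries its concatenated width 2 * 192 = 384
  expect_equal(lay$dec1.c1, c(3, 384 + 384, 232))
  expect_equal(lay$dec4.c2, c(3, 29, 29))
  expect_equal(lay$pred, c(3, 29, 2))
})

test_that("model_size agrees between config and built model", {
  cfg <- tiny_cfg()
  m <- build_rgc_unet(cfg, seed = 1)
  expect_equal(model_size(cfg)$param_count, model_size(m)$param_count)
  expect_equal(model_size(m)$bytes, 4 * model_size(m)$param_count)
})

test_that("all intermediate activations between encoder and head are binary", {
  cfg <- tiny_cfg(t_steps = 3)
  m <- build_rgc_unet(cfg, seed = 2)
  set.seed(2)
  x <- matrix(runif(32 * 32 * 3), 32 * 32, 3)
  fwd <- unet_forward(m, x, 32, 32)
  is_bin <- function(lst) all(vapply(lst, function(s) all(s %in% c(0, 1)),
                                     logical(1)))
  for (st in fwd$cache$stages) {
    expect_true(is_bin(st$n1$spikes))
    expect_true(is_bin(st$n2$spikes))
  }
  expect_true(is_bin(fwd$cache$ppm$n$spikes))
  for (dc in fwd$cache$dec) {
    expect_true(is_bin(dc$n1$spikes))
    expect_true(is_bin(dc$n2$spikes))
  }
  # the prediction head is real-valued evidence, not spikes
  expect_equal(dim(fwd$evidence), c(32 * 32, 2))
  expect_equal(length(fwd$logits), 3)
  expect_equal(fwd$evidence, Reduce(`+`, fwd$logits))
})

test_that("spatial contract holds at multiple input sizes", {
  cfg <- tiny_cfg(t_steps = 1)
  m <- build_rgc_unet(cfg, seed = 3)
  for (s in c(32, 64)) {
    set.seed(s)
    x <- matrix(runif(s * s * 3), s * s, 3)
    fwd <- unet_forward(m, x, s, s)
    expect_equal(nrow(fwd$evidence), s * s)
    # bottleneck at 1/16 resolution with the widest plan entry
    expect_equal(dim(fwd$cache$ppm$n$spikes[[1]]),
                 c((s / 16)^2, cfg$channel_plan[5]))
  }
  expect_error(unet_forward(m, matrix(0.5, 30 * 30, 3), 30, 30))
})

test_that("skip-concatenation doubles channels, processed spikes first", {
  np <- neuron_params()
  set.seed(4)
  sp <- rep(list(matrix(sample(0:1, 16 * 4, replace = TRUE), 16, 4)), 2)
  cv1 <- list(w = matrix(0, 9 * 4, 4), b = rep(10, 4))   # always fires
  cv2 <- list(w = matrix(0, 9 * 4, 4), b = rep(-1, 4))   # never fires
  out <- sc_forward(sp, cv1, cv2, 4, 4, 3, np)$out
  expect_equal(ncol(out[[1]]), 8)
  # with the chosen biases the processed half is all zeros (second conv never
  # fires) and the input half is the original spike pattern
  expect_equal(out[[1]][, 5:8], sp[[1]])
  expect_equal(sum(out[[1]][, 1:4]), 0)
})

test_that("gradients reach every parameter of the tiny network", {
  cfg <- tiny_cfg(t_steps = 2)
  m <- build_rgc_unet(cfg, seed = 5)
  set.seed(5)
  x <- matrix(runif(32 * 32 * 3), 32 * 32, 3)
  fwd <- unet_forward(m, x, 32, 32)
  lab <- sample(0:1, 32 * 32, replace = TRUE)
  lg <- rgcsnn:::.ce_loss_grad(fwd$evidence, lab)
  g <- unet_backward(m, fwd, lg$grad)
  expect_setequal(names(g), names(m$params))
  for (nm in names(g)) {
    expect_equal(dim(g[[nm]]), dim(m$params[[nm]]), info = nm)
    expect_true(any(g[[nm]] != 0), info = nm)
  }
})

test_that("whole-network backward matches finite differences (relaxed)", {
  cfg <- tiny_cfg(t_steps = 2)
  m <- build_rgc_unet(cfg, seed = 6)
  set.seed(6)
  # jitter biases so no unit sits exactly on the surrogate-window edge
  for (nm in grep("\\.b$", names(m$params), value = TRUE))
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), sd = 0.05)
  x <- matrix(runif(16 * 16 * 3), 16 * 16, 3)
  lab <- sample(0:1, 16 * 16, replace = TRUE)
  lossfun <- function(mm) {
    fw <- unet_forward(mm, x, 16, 16, relaxed = TRUE)
    rgcsnn:::.ce_loss_grad(fw$evidence, lab)$loss
  }
  fwd <- unet_forward(m, x, 16, 16, relaxed = TRUE)
  lg <- rgcsnn:::.ce_loss_grad(fwd$evidence, lab)
  g <- unet_backward(m, fwd, lg$grad)
  eps <- 1e-6
  set.seed(7)
  for (trial in 1:15) {
    nm <- sample(names(m$params), 1)
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 info = paste(nm, i))
  }
})

test_that("module-level wrappers chain into the full forward pass", {
  cfg <- tiny_cfg(t_steps = 2)
  m <- build_rgc_unet(cfg, seed = 8)
  set.seed(8)
  img <- rand_image(32, 32, seed = 8)
  enc_w <- list(enc1 = list(w = m$params$enc1.w, b = m$params$enc1.b),
                enc2 = list(w = m$params$enc2.w, b = m$params$enc2.b))
  tr <- encode(img, enc_w, cfg$encoder)
  ctr <- contracting_forward(m, tr)
  expect_equal(ctr$bottleneck$C, cfg$channel_plan[5])
  expect_equal(ctr$bottleneck$H, 2)          # 32 / 16
  expect_length(ctr$skips, 4)
  pp <- ppm_forward(m, ctr$bottleneck)
  expect_equal(attr(pp, "concat_channels"),
               cfg$channel_plan[5] + 4 * cfg$ppm_branch_channels)
  out <- expansive_forward(m, pp, ctr$skips)
  expect_equal(dim(out$evidence), c(32 * 32, 2))
  # matches the monolithic forward exactly
  fwd <- unet_forward(m, matrix(img, 32 * 32, 3), 32, 32)
  expect_equal(out$evidence, fwd$evidence, tolerance = 1e-12)
})

test_that("decode_prediction accumulates evidence and breaks ties low", {
  l1 <- matrix(c(1, 0, 2, 0,
                 0, 1, 2, 5), 4, 2)
  out <- decode_prediction(list(l1, l1), 2, 2)
  expect_s3_class(out, "segmentation_output")
  expect_equal(out$spike_counts, l1 + l1)
  expect_equal(as.vector(out$mask), c(0, 1, 0, 1))   # row 3 ties -> class 0
  expect_equal(dim(out$counts_array), c(2, 2, 2))
  # array layout spot check: counts_array[class, r, c]
  expect_equal(out$counts_array[1, 2, 1], 0)
  expect_equal(out$counts_array[2, 2, 2], 10)
})

test_that("classifier topologies follow the published stage lists", {
  st <- rgcsnn:::.classifier_stages
  expect_equal(st$mnist, c("encode", "rgc", "ap", "rgc", "ap", "rgc", "rgc",
                           "out"))
  expect_equal(st$n_mnist, c("encode", "rgc", "rgc", "out"))
  expect_equal(st$dvs128, c("encode", "ap", "rgc", "rgc", "ap", "rgc", "ap",
                            "rgc", "out"))
  m <- build_classifier("mnist", "rgc", input_size = 16, width = 4, seed = 9)
  set.seed(9)
  x <- matrix(runif(256), 256, 1)
  f <- rgcsnn:::classifier_forward(m, x)
  expect_length(f$evidence, 10)
  g <- rgcsnn:::classifier_backward(m, f, runif(10) - 0.5)
  expect_setequal(names(g), names(m$params))
})

test_that("classifier backward matches finite differences (relaxed)", {
  m <- build_classifier("n_mnist", "lif", input_size = 8, width = 3,
                        t_steps = 2, seed = 10)
  set.seed(10)
  for (nm in grep("\\.b$", names(m$params), value = TRUE))
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), sd = 0.05)
  x <- matrix(runif(64), 64, 1)
  lossfun <- function(mm) {
    f <- rgcsnn:::classifier_forward(mm, x, relaxed = TRUE)
    rgcsnn:::.ce_loss_grad(matrix(f$evidence, 1), 3L)$loss
  }
  f <- rgcsnn:::classifier_forward(m, x, relaxed = TRUE)
  lg <- rgcsnn:::.ce_loss_grad(matrix(f$evidence, 1), 3L)
  g <- rgcsnn:::classifier_backward(m, f, drop(lg$grad))
  eps <- 1e-6
  set.seed(11)
  for (trial in 1:10) {
    nm <- sample(names(m$params), 1)
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4, info = paste(nm, i))
  }
})
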