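test_that("train_config validates its arguments", {
  ctl <- train_config(lr = 1e-3, epochs = 2)
  expect_s3_class(ctl, "train_config")
  expect_error(train_config(lr = -1))
  expect_error(train_config(epochs = 0))
  expect_error(train_config(loss = "hinge"))
})

test_that("cross-entropy matches closed forms", {
  # uniform evidence over 2 classes -> log 2 regardless of labels
  ev <- matrix(0, 10, 2)
  expect_equal(ce_loss(ev, rep(0L, 10)), log(2), tolerance = 1e-12)
  # strong evidence for the true class -> loss near 0
  ev2 <- matrix(c(50, 0), 10, 2, byrow = TRUE)
  expect_lt(ce_loss(ev2, rep(0L, 10)), 1e-8)
  # the array entry point (n_classes x H x W) agrees with the matrix one
  set.seed(29)
  ev3 <- matrix(rnorm(8), 4, 2)
  a3 <- array(t(ev3), c(2, 2, 2))           # [class, row, col], column-major

  lab <- c(0L, 1L, 1L, 0L)
  expect_equal(ce_loss(a3, lab), ce_loss(ev3, lab), tolerance = 1e-12)
  expect_error(ce_loss(ev, rep(2L, 10)), "class range")
})

test_that("loss gradient matches finite differences and sums to zero", {
  set.seed(30)
  ev <- matrix(rnorm(12), 6, 2)
  lab <- sample(0:1, 6, replace = TRUE)
  lg <- rgcsnn:::.ce_loss_grad(ev, lab)
  expect_equal(rowSums(lg$grad), rep(0, 6), tolerance = 1e-12)
  eps <- 1e-6
  for (i in c(1, 7, 12)) {
    ep <- ev; ep[i] <- ep[i] + eps
    en <- ev; en[i] <- en[i] - eps
    num <- (rgcsnn:::.ce_loss_grad(ep, lab)$loss -
            rgcsnn:::.ce_loss_grad(en, lab)$loss) / (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-6)
  }
})

test_that("the first Adam step moves each coordinate by about lr", {
  ctl <- train_config(lr = 0.01, epochs = 1)
  params <- list(w = matrix(c(1, -2, 3, 4), 2, 2))
  grads <- list(w = matrix(c(0.5, -0.1, 2, -3), 2, 2))
  st <- rgcsnn:::adam_state()
  upd <- rgcsnn:::adam_step(params, grads, st, ctl)
  step <- upd$params$w - params$w
  # bias-corrected first step is -lr * sign(g) up to the eps stabiliser
  expect_equal(step, -0.01 * sign(grads$w), tolerance = 1e-4)
  expect_equal(upd$state$t, 1)
})

test_that("fit_rgcsnn with lr = 0 evaluates but never updates", {
  cfg <- tiny_cfg(t_steps = 2)
  items <- generate_wounds(synth_config(n_images = 2, size = 16, seed = 31))
  ctl <- train_config(lr = 0, epochs = 1, batch_size = 2, seed = 31,
                      online_jitter = FALSE)
  m <- fit_rgcsnn(items, test = items, config = cfg, control = ctl)
  set.seed(31)
  ref <- build_rgc_unet(cfg)
  expect_equal(m$params, ref$params)
  expect_equal(nrow(m$history), 1)
  expect_false(is.na(m$history$test_pa[1]))
})

test_that("fitting is reproducible under the control seed", {
  cfg <- tiny_cfg(t_steps = 2)
  items <- generate_wounds(synth_config(n_images = 4, size = 16, seed = 32))
  ctl <- train_config(lr = 1e-3, epochs = 2, batch_size = 2, seed = 32,
                      online_jitter = TRUE)
  m1 <- fit_rgcsnn(items, config = cfg, control = ctl)
  m2 <- fit_rgcsnn(items, config = cfg, control = ctl)
  expect_equal(m1$params, m2$params)
  expect_equal(m1$history, m2$history)
})

test_that("training reduces the loss on a tiny problem", {
  cfg <- tiny_cfg(t_steps = 2)
  items <- generate_wounds(synth_config(n_images = 2, size = 16, seed = 33))
  ctl <- train_config(lr = 5e-3, epochs = 20, batch_size = 2, seed = 33,
                      online_jitter = FALSE)
  m <- fit_rgcsnn(items, config = cfg, control = ctl)
  h <- m$history$train_loss
  # average over epochs to be robust to mini-batch noise
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)) - 0.1)
  expect_s3_class(m, "rgc_snn")
  expect_false(is.null(m$history))
})

test_that("fit_classifier records a history and respects its seed", {
  data <- synth_digits(n = 24, size = 8, seed = 34, jitter = 1)
  tr <- data[1:16]; te <- data[17:24]
  ctl <- train_config(lr = 1e-3, epochs = 2, batch_size = 8, seed = 34,
                      online_jitter = FALSE)
  m0 <- build_classifier("n_mnist", "rgc", input_size = 8, width = 4,
                         t_steps = 2, seed = 34)
  m1 <- fit_classifier(m0, tr, te, ctl)
  m2 <- fit_classifier(m0, tr, te, ctl)
  expect_equal(m1$params, m2$params)
  expect_equal(nrow(m1$history), 2)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_true(all(m1$history$test_acc >= 0 & m1$history$test_acc <= 1))
})

test_that("early stopping halts once the target pixel accuracy is reached", {
  cfg <- tiny_cfg(t_steps = 2)
  items <- generate_wounds(synth_config(n_images = 2, size = 16, seed = 35))
  ctl <- train_config(lr = 1e-3, epochs = 50, batch_size = 2, seed = 35,
                      online_jitter = FALSE, stop_pa = 0)   # trivially met
  m <- fit_rgcsnn(items, test = items, config = cfg, control = ctl)
  expect_equal(nrow(m$history), 1)
})
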