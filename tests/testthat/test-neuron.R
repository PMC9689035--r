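test_that("parameter constructor validates its arguments", {
  expect_s3_class(neuron_params(), "neuron_params")
  expect_error(neuron_params(v_th = 0))
  expect_error(neuron_params(a1 = -1))
  expect_error(neuron_params(lif_decay = 0))
  expect_error(neuron_params(lif_decay = 1.5))
  expect_error(neuron_params(mode = "izhikevich"))
})

test_that("ion-channel current matches the closed form", {
  p <- neuron_params(g_na = 0.3, g_k = 0.2, g_l = 0.1)
  st <- membrane_state(c(2, 2), p)
  st$u <- matrix(c(-0.5, 0, 0.5, 1), 2, 2)
  st$m <- matrix(0.8, 2, 2); st$n <- matrix(0.4, 2, 2); st$h <- matrix(0.9, 2, 2)
  want <- 0.3 * 0.8^3 * 0.9 * (st$u - 1) + 0.2 * 0.4^4 * (st$u + 1) +
    0.1 * st$u
  expect_equal(ion_channel_current(st, p), want, tolerance = 1e-12)
  st$m <- matrix(1.5, 2, 2)
  expect_error(ion_channel_current(st, p), "gating")
  st$m <- matrix(1, 2, 2); st$u[1] <- NaN
  expect_error(ion_channel_current(st, p), "finite")
})

test_that("fire_and_reset fires strictly above threshold and soft-resets", {
  p <- neuron_params()
  u <- matrix(c(0.2, 0.5, 0.5000001, 1.3), 1, 4)
  fr <- fire_and_reset(u, p)
  expect_equal(as.vector(fr$spikes), c(0, 0, 1, 1))
  expect_equal(as.vector(fr$u_after), c(0.2, 0.5, 0.0000001, 0.8),
               tolerance = 1e-9)
})

test_that("constant-input RGC trace follows the hand-iterated update", {
  # Eq.-style soft-reset iteration, written out independently of the package:
  # u <- u + (I - g_l*(u - e_l)) - s_prev*v_th; s <- u > v_th
  p <- neuron_params(g_l = 0)
  st <- membrane_state(c(1, 1), p)
  u_hand <- 0; s_hand <- 0
  got_s <- got_u <- want_s <- want_u <- numeric(8)
  for (t in 1:8) {
    u_hand <- u_hand + 0.3 - s_hand * 0.5
    s_hand <- as.numeric(u_hand > 0.5)
    want_u[t] <- u_hand; want_s[t] <- s_hand
    r <- rgc_step(st, matrix(0.3, 1, 1), p)
    st <- r$state
    got_s[t] <- r$spikes[1, 1]; got_u[t] <- st$u[1, 1]
  }
  expect_equal(got_u, want_u, tolerance = 1e-12)
  expect_equal(got_s, want_s)
  # the resulting spike steps (soft reset carries the surplus, so the fourth
  # inter-spike interval shortens to one step)
  expect_equal(which(got_s == 1), c(2L, 4L, 6L, 7L))
  expect_equal(round(want_u, 10), c(0.3, 0.6, 0.4, 0.7, 0.5, 0.8, 0.6, 0.4))
})

test_that("closed-form spike times hold for constant input", {
  # with input c, g = 0 and soft reset, the n-th spike lands at
  # floor(n * v_th / c) + 1
  p <- neuron_params(g_l = 0)
  set.seed(21)
  for (rep in 1:10) {
    c0 <- runif(1, 0.05, 0.45)
    n_steps <- 60
    fw <- rgcsnn:::neuron_forward(rep(list(matrix(c0, 1, 1)), n_steps), p)
    got <- which(vapply(fw$spikes, function(s) s[1, 1], numeric(1)) == 1)
    ratio <- seq_along(got) * p$v_th / c0
    if (any(abs(ratio - round(ratio)) < 1e-9)) next  # skip knife-edge draws
    expect_equal(got, floor(ratio) + 1)
  }
})

test_that("a positive leak slows the spike rate", {
  cur <- rep(list(matrix(0.3, 1, 1)), 20)
  n_leak <- sum(vapply(rgcsnn:::neuron_forward(cur, neuron_params(g_l = 0.3))$spikes,
                       sum, numeric(1)))
  n_free <- sum(vapply(rgcsnn:::neuron_forward(cur, neuron_params(g_l = 0))$spikes,
                       sum, numeric(1)))
  expect_lt(n_leak, n_free)
})

test_that("LIF trace follows the decayed hard-reset update", {
  p <- neuron_params(mode = "lif")
  st <- membrane_state(c(1, 1), p)
  u_hand <- 0; s_hand <- 0
  for (t in 1:9) {
    u_hand <- 0.5 * u_hand * (1 - s_hand) + 0.3
    s_hand <- as.numeric(u_hand > 0.5)
    r <- lif_step(st, matrix(0.3, 1, 1), p)
    st <- r$state
    expect_equal(st$u[1, 1], u_hand, tolerance = 1e-12)
    expect_equal(r$spikes[1, 1], s_hand)
  }
})

test_that("frozen gating is the default and relaxation moves toward x_inf", {
  p <- neuron_params()
  st <- membrane_state(c(1, 1), p)
  st$u <- matrix(2, 1, 1)
  expect_identical(update_gating(st, p), st)
  p2 <- neuron_params(gate_rate = 0.5, m0 = 0.2, n0 = 0.2, h0 = 0.2)
  st2 <- membrane_state(c(1, 1), p2)
  st2$u <- matrix(2, 1, 1)                 # far above gate_theta: x_inf ~ 1
  st3 <- update_gating(st2, p2)
  expect_gt(st3$m[1, 1], st2$m[1, 1])
  expect_gt(st3$n[1, 1], st2$n[1, 1])
  expect_lt(st3$h[1, 1], st2$h[1, 1])      # h relaxes toward 1 - x_inf
  expect_true(all(c(st3$m, st3$n, st3$h) >= 0 & c(st3$m, st3$n, st3$h) <= 1))
})

test_that("surrogate gradient is a centred window of unit integral", {
  for (a1 in c(0.5, 1, 2)) {
    p <- neuron_params(a1 = a1)
    u <- seq(-3, 3.5, by = 1e-4)
    g <- surrogate_grad(u, p)
    expect_equal(sum(g) * 1e-4, 1, tolerance = 1e-3)
    expect_equal(max(g), 1 / a1)
    expect_true(all(g[abs(u - 0.5) > a1 / 2 + 1e-3] == 0))
  }
})

test_that("neuron BPTT backward matches finite differences on a 2-unit net", {
  for (mode in c("rgc", "lif")) {
  p <- neuron_params(mode = mode)
  set.seed(22)
  tt <- 2
  cur <- lapply(seq_len(tt), function(t) matrix(runif(2, 0.2, 0.9), 1, 2))
  w_out <- matrix(rnorm(2), 2, 1)
  lossfun <- function(cl) {
    fw <- rgcsnn:::neuron_forward(cl, p, relaxed = TRUE)
    sum(vapply(fw$spikes, function(s) sum(s %*% w_out), numeric(1)))
  }
  fw <- rgcsnn:::neuron_forward(cur, p, relaxed = TRUE)
  g_sp <- rep(list(matrix(w_out, 1, 2)), tt)
  g_cur <- rgcsnn:::neuron_backward(fw, g_sp)
  eps <- 1e-6
  for (t in seq_len(tt)) for (i in 1:2) {
    cp <- cur; cp[[t]][i] <- cp[[t]][i] + eps
    cm <- cur; cm[[t]][i] <- cm[[t]][i] - eps
    num <- (lossfun(cp) - lossfun(cm)) / (2 * eps)
    expect_equal(g_cur[[t]][i], num, tolerance = 1e-4)
  }
  }
})

test_that("relaxed and binary forward agree away from the threshold window", {
  p <- neuron_params(a1 = 1e-6)
  cur <- rep(list(matrix(c(0.3, 0.8), 1, 2)), 4)
  fb <- rgcsnn:::neuron_forward(cur, p)
  fr <- rgcsnn:::neuron_forward(cur, p, relaxed = TRUE)
  for (t in 1:4) expect_equal(fb$spikes[[t]], fr$spikes[[t]])
})
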