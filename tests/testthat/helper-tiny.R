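# Shared helpers: a reduced-width network configuration and random inputs
# small enough for fast unit tests.

tiny_cfg <- function(t_steps = 2, plan = c(2, 4, 8, 16, 32)) {
  network_config(channel_plan = plan, t_steps = t_steps,
                 encoder = encoder_config(out_channels = plan[1],
                                          t_steps = t_steps))
}

rand_image <- function(H, W, C = 3, seed = 1) {
  set.seed(seed)
  array(runif(H * W * C), c(H, W, C))
}

rand_item <- function(H, W, seed = 1) {
  set.seed(seed)
  labeled_image(array(runif(H * W * 3), c(H, W, 3)),
                matrix(sample(0:1, H * W, replace = TRUE), H, W),
                paste0("t", seed))
}

# Naive O(H W k^2 Cin Cout) same-padded correlation, the oracle for conv2d.
naive_conv <- function(x, weight, bias, H, W, k) {
  cin <- ncol(x)
  cout <- length(bias)
  p <- (k - 1) %/% 2
  wa <- array(weight, c(k, k, cin, cout))
  xa <- array(x, c(H, W, cin))
  out <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      acc <- bias[co]
      for (dr in 0:(k - 1)) for (dc in 0:(k - 1)) {
        rr <- r + dr - p; c2 <- cc + dc - p
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W)
          acc <- acc + sum(xa[rr, c2, ] * wa[dr + 1, dc + 1, , co])
      }
      out[r, cc, co] <- acc
    }
  }
  matrix(out, H * W, cout)
}
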