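# Low-level tensor primitives for the spiking U-net.
#
# Feature maps are stored as (H*W) x C double matrices with pixels in
# column-major order (row index fastest), matching R's array layout, so a map
# can be reshaped to/from an H x W x C array with dim<- alone. Convolutions are
# evaluated as im2col gathers followed by BLAS matrix products; every spatial
# operator has a hand-written adjoint used by backpropagation.

.op_cache <- new.env(parent = emptyenv())

#' @keywords internal
.cache_get <- function(key, make) {
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- make()
  .op_cache[[key]]
}

# Gather indices for a same-padded k x k convolution on an H x W grid:
# an (H*W) x k^2 matrix of source indices per kernel offset (row offset
# fastest, matching the flattened weight layout); out-of-range taps point at
# a sentinel zero row H*W + 1.
conv_prep <- function(H, W, k) {
  key <- paste("conv", H, W, k, sep = "_")
  .cache_get(key, function() {
    p <- (k - 1L) %/% 2L
    rs <- rep.int(seq_len(H), W)
    cs <- rep(seq_len(W), each = H)
    cols <- matrix(0L, H * W, k * k)
    o <- 0L
    for (dc in 0:(k - 1L)) {
      for (dr in 0:(k - 1L)) {
        o <- o + 1L
        rr <- rs + dr - p
        cc <- cs + dc - p
        idx <- (cc - 1L) * H + rr
        idx[rr < 1L | rr > H | cc < 1L | cc > W] <- H * W + 1L
        cols[, o] <- idx
      }
    }
    list(p = p, cols = as.vector(cols))
  })
}

# x: (H*W) x Cin. Returns (H*W) x (k^2 * Cin) patch matrix.
im2col <- function(x, H, W, k) {
  prep <- conv_prep(H, W, k)
  C <- ncol(x)
  m <- rbind(x, 0)[prep$cols, , drop = FALSE]
  dim(m) <- c(H * W, k * k * C)
  m
}

# weight: (k^2*Cin) x Cout matrix (flattened [dr, dc, cin] rows); bias: Cout.
conv2d <- function(x, weight, bias, H, W, k) {
  out <- im2col(x, H, W, k) %*% weight
  out + rep(bias, each = H * W)
}

# The adjoint of a same-padded correlation is a same-padded correlation with
# the spatially flipped kernel and cin/cout swapped: reorder the weight so
# grad_input = im2col(g) %*% flip(weight).
.flip_weight <- function(weight, k) {
  cin <- nrow(weight) %/% (k * k)
  cout <- ncol(weight)
  wa <- array(weight, c(k * k, cin, cout))
  wf <- wa[rev(seq_len(k * k)), , , drop = FALSE]
  matrix(aperm(wf, c(1L, 3L, 2L)), k * k * cout, cin)
}

# Adjoints. x is the cached forward input; g the (H*W) x Cout output gradient.
conv2d_grad_input <- function(g, weight, H, W, k, wflip = NULL) {
  if (is.null(wflip)) wflip <- .flip_weight(weight, k)
  im2col(g, H, W, k) %*% wflip
}

conv2d_grad_weight <- function(x, g, H, W, k) {
  list(w = crossprod(im2col(x, H, W, k), g), b = colSums(g))
}

# Fused backward for one conv: a single im2col of the output gradient feeds
# both the input gradient (flipped-kernel product) and the weight gradient
# (crossprod with the input, offsets un-flipped afterwards).
conv2d_backward <- function(x, g, weight, H, W, k, wflip = NULL) {
  if (is.null(wflip)) wflip <- .flip_weight(weight, k)
  cin <- ncol(x)
  cout <- ncol(g)
  gcol <- im2col(g, H, W, k)                    # (H*W) x (k^2*Cout)
  gx <- gcol %*% wflip
  gwp <- crossprod(x, gcol)                     # Cin x (k^2*Cout)
  dim(gwp) <- c(cin, k * k, cout)
  gwp <- gwp[, rev(seq_len(k * k)), , drop = FALSE]
  gw <- matrix(aperm(gwp, c(2L, 1L, 3L)), k * k * cin, cout)
  list(x = gx, w = gw, b = colSums(g))
}

# 2x2 average pooling (stride 2). H, W must be even.
pool_prep <- function(H, W) {
  key <- paste("pool", H, W, sep = "_")
  .cache_get(key, function() {
    H2 <- H %/% 2L
    W2 <- W %/% 2L
    rs <- rep.int(seq_len(H2), W2)
    cs <- rep(seq_len(W2), each = H2)
    i1 <- (2L * cs - 2L) * H + (2L * rs - 1L)
    list(i1 = i1, i2 = i1 + 1L, i3 = i1 + H, i4 = i1 + H + 1L)
  })
}

avgpool2 <- function(x, H, W) {
  p <- pool_prep(H, W)
  (x[p$i1, , drop = FALSE] + x[p$i2, , drop = FALSE] +
   x[p$i3, , drop = FALSE] + x[p$i4, , drop = FALSE]) / 4
}

avgpool2_grad <- function(g, H, W) {
  p <- pool_prep(H, W)
  gx <- matrix(0, H * W, ncol(g))
  q <- g / 4
  gx[p$i1, ] <- q
  gx[p$i2, ] <- q
  gx[p$i3, ] <- q
  gx[p$i4, ] <- q
  gx
}

# Adaptive average pooling H x W -> b x b as a dense (b^2) x (H*W) operator
# (bin edges floor(i*s/b) .. ceil((i+1)*s/b), the standard adaptive rule).
.adaptive_pool_1d <- function(s, b) {
  P1 <- matrix(0, b, s)
  for (i in 0:(b - 1L)) {
    lo <- floor(i * s / b) + 1L
    hi <- ceiling((i + 1L) * s / b)
    P1[i + 1L, lo:hi] <- 1 / (hi - lo + 1L)
  }
  P1
}

adaptive_pool_matrix <- function(H, W, b) {
  key <- paste("apool", H, W, b, sep = "_")
  .cache_get(key, function() {
    # column-major pixel order (row fastest): out = (Pc %x% Pr) %*% vec(X)
    kronecker(.adaptive_pool_1d(W, b), .adaptive_pool_1d(H, b))
  })
}

# Bilinear interpolation weights (half-pixel centres, edges clamped).
interp_matrix <- function(n_in, n_out) {
  key <- paste("interp", n_in, n_out, sep = "_")
  .cache_get(key, function() {
    R <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * n_in / n_out - 0.5
      src <- min(max(src, 0), n_in - 1)
      i0 <- floor(src)
      w <- src - i0
      i1 <- min(i0 + 1, n_in - 1)
      R[i, i0 + 1] <- R[i, i0 + 1] + (1 - w)
      R[i, i1 + 1] <- R[i, i1 + 1] + w
    }
    R
  })
}

# Apply separable row/column operators My (Hout x H) and Mx (Wout x W) to a
# (H*W) x C map; used for bilinear resizing (forward) and its adjoint
# (transposed matrices).
apply_separable <- function(x, H, W, My, Mx) {
  C <- ncol(x)
  H2 <- nrow(My)
  W2 <- nrow(Mx)
  m <- My %*% matrix(x, H, W * C)               # H2 x (W*C)
  a <- aperm(array(m, c(H2, W, C)), c(2L, 1L, 3L))
  m2 <- Mx %*% matrix(a, W, H2 * C)             # W2 x (H2*C)
  a2 <- aperm(array(m2, c(W2, H2, C)), c(2L, 1L, 3L))
  dim(a2) <- c(H2 * W2, C)
  a2
}

resize_bilinear <- function(x, H, W, Hout, Wout) {
  apply_separable(x, H, W, interp_matrix(H, Hout), interp_matrix(W, Wout))
}

resize_bilinear_grad <- function(g, H, W, Hout, Wout) {
  apply_separable(g, Hout, Wout, t(interp_matrix(H, Hout)), t(interp_matrix(W, Wout)))
}

# Nearest-neighbour resize for label masks (values preserved exactly).
resize_nearest_idx <- function(n_in, n_out) {
  i <- pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
  as.integer(i)
}

resize_nearest <- function(m, Hout, Wout) {
  m[resize_nearest_idx(nrow(m), Hout), resize_nearest_idx(ncol(m), Wout), drop = FALSE]
}

# Weight initialisation: He-style normal scaled by fan-in.
init_conv <- function(k, cin, cout, rng_sd = sqrt(2 / (k * k * cin))) {
  list(w = matrix(stats::rnorm(k * k * cin * cout, sd = rng_sd), k * k * cin, cout),
       b = numeric(cout))
}

init_fc <- function(nin, nout) {
  list(w = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}
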