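#' Synthetic wound-image generator configuration
#'
#' Produces labelled images emulating the salient features of clinical burn
#' photographs: a skin-tone background with low-frequency texture, one to a
#' few irregular reddish-brown lesion regions (class 0), and additive device
#' noise. The lesion colour is blended toward the skin tone by the
#' \code{difficulty} knob so segmentation is not trivially colour-separable.
#'
#' @param n_images number of images.
#' @param size square side in pixels; must be divisible by 16 (network
#'   constraint).
#' @param seed RNG seed; generation is fully deterministic under it.
#' @param skin_r,skin_g,skin_b per-channel ranges of the base skin tone.
#' @param lesion_count range (min, max) of lesions per image.
#' @param lesion_radius range of lesion radii as a fraction of \code{size}.
#' @param irregularity amplitude of the radial boundary perturbation (0 gives
#'   exact ellipses/circles).
#' @param difficulty in [0, 1): 0 paints lesions in a pure burn colour,
#'   larger values blend them toward the local skin tone.
#' @param texture_amp amplitude of the low-frequency background texture.
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_images = 200, size = 64, seed = 1,
                         skin_r = c(0.55, 0.85), skin_g = c(0.35, 0.65),
                         skin_b = c(0.25, 0.50),
                         lesion_count = c(1, 3),
                         lesion_radius = c(0.10, 0.22),
                         irregularity = 0.35, difficulty = 0.25,
                         texture_amp = 0.05, noise_sigma = 0.02) {
  stopifnot(size %% 16 == 0, n_images >= 0, irregularity >= 0,
            difficulty >= 0, difficulty < 1)
  structure(list(n_images = n_images, size = size, seed = seed,
                 skin_r = skin_r, skin_g = skin_g, skin_b = skin_b,
                 lesion_count = lesion_count, lesion_radius = lesion_radius,
                 irregularity = irregularity, difficulty = difficulty,
                 texture_amp = texture_amp, noise_sigma = noise_sigma),
            class = "synth_config")
}

# One irregular lesion membership test over the pixel grid.
.lesion_mask <- function(S, cx, cy, a, b, phi, irregularity) {
  r <- rep.int(seq_len(S), S)
  c <- rep(seq_len(S), each = S)
  dy <- r - cy
  dx <- c - cx
  u <- (cos(phi) * dx + sin(phi) * dy) / a
  v <- (-sin(phi) * dx + cos(phi) * dy) / b
  rho <- sqrt(u^2 + v^2)
  if (irregularity > 0) {
    th <- atan2(v, u)
    amp <- stats::rnorm(4, sd = c(0.5, 0.35, 0.25, 0.2))
    pha <- stats::runif(4, 0, 2 * pi)
    s <- rep(0, length(th))
    for (k in 2:5) s <- s + amp[k - 1] * cos(k * th + pha[k - 1])
    thresh <- pmax(1 + irregularity * s / 2, 0.2)
  } else thresh <- 1
  rho <= thresh
}

#' Generate synthetic wound images
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list of \code{\link{labeled_image}}s; masks are 0 inside lesions,
#'   1 outside.
#' @export
generate_wounds <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  S <- cfg$size
  out <- vector("list", cfg$n_images)
  burn_col <- c(0.45, 0.12, 0.10)
  for (i in seq_len(cfg$n_images)) {
    tone <- c(stats::runif(1, cfg$skin_r[1], cfg$skin_r[2]),
              stats::runif(1, cfg$skin_g[1], cfg$skin_g[2]),
              stats::runif(1, cfg$skin_b[1], cfg$skin_b[2]))
    # low-frequency texture from an upsampled coarse noise grid
    coarse <- matrix(stats::rnorm(16, sd = cfg$texture_amp), 4, 4)
    tex <- resize_bilinear(matrix(coarse, 16, 1), 4, 4, S, S)
    img <- matrix(rep(tone, each = S * S), S * S, 3) +
      matrix(tex, S * S, 3)
    mask <- rep(1L, S * S)
    n_lesions <- if (cfg$lesion_count[1] >= cfg$lesion_count[2])
      cfg$lesion_count[1]
    else sample(cfg$lesion_count[1]:cfg$lesion_count[2], 1)
    for (l in seq_len(n_lesions)) {
      a <- stats::runif(1, cfg$lesion_radius[1], cfg$lesion_radius[2]) * S
      b <- if (cfg$irregularity > 0) a * (1 + stats::runif(1, -0.3, 0.3)) else a
      margin <- ceiling(max(a, b) * (1 + cfg$irregularity))
      margin <- min(margin, S %/% 2 - 1)
      cx <- stats::runif(1, margin + 1, S - margin)
      cy <- stats::runif(1, margin + 1, S - margin)
      phi <- stats::runif(1, 0, pi)
      inside <- .lesion_mask(S, cx, cy, a, b, phi, cfg$irregularity)
      mask[inside] <- 0L
      col <- (1 - cfg$difficulty) * (burn_col + stats::rnorm(3, sd = 0.03)) +
        cfg$difficulty * tone
      img[inside, ] <- matrix(rep(col, each = sum(inside)), ncol = 3)
    }
    img <- img + matrix(stats::rnorm(S * S * 3, sd = cfg$noise_sigma), S * S, 3)
    img <- pmin(pmax(img, 0), 1)
    out[[i]] <- labeled_image(array(img, c(S, S, 3)), matrix(mask, S, S),
                              sprintf("synth%04d", i))
  }
  out
}

#' Deterministic train/test split of a synthetic dataset
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param train_frac fraction of images assigned to the training split
#'   (0 < frac < 1).
#' @return list with disjoint \code{train} and \code{test} lists whose union
#'   is the full dataset.
#' @export
generate_split <- function(cfg = synth_config(), train_frac = 0.8) {
  stopifnot(train_frac > 0, train_frac < 1)
  items <- generate_wounds(cfg)
  n <- length(items)
  n_train <- round(train_frac * n)
  perm <- sample.int(n)    # continues the generator's seeded stream
  list(train = items[perm[seq_len(n_train)]],
       test = items[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

# -- synthetic digit task for the classifier benchmark ------------------------

.seven_segments <- list(
  "0" = c("A", "B", "C", "D", "E", "F"),
  "1" = c("B", "C"),
  "2" = c("A", "B", "G", "E", "D"),
  "3" = c("A", "B", "G", "C", "D"),
  "4" = c("F", "G", "B", "C"),
  "5" = c("A", "F", "G", "C", "D"),
  "6" = c("A", "F", "G", "E", "C", "D"),
  "7" = c("A", "B", "C"),
  "8" = c("A", "B", "C", "D", "E", "F", "G"),
  "9" = c("A", "B", "F", "G", "C", "D"))

# Segment rectangles in glyph-relative coordinates (x across, y down), with
# thickness t.
.segment_rect <- function(seg, t) {
  switch(seg,
    A = c(0, 1, 0, t),
    G = c(0, 1, 0.5 - t / 2, 0.5 + t / 2),
    D = c(0, 1, 1 - t, 1),
    F = c(0, t, 0, 0.5),
    E = c(0, t, 0.5, 1),
    B = c(1 - t, 1, 0, 0.5),
    C = c(1 - t, 1, 0.5, 1))
}

#' Generate a digit-style synthetic classification dataset
#'
#' Renders seven-segment digits 0-9 at random sub-pixel offsets with intensity
#' jitter and additive noise; a self-contained stand-in for handwritten-digit
#' benchmarks so the classifier topologies can be exercised without downloads.
#'
#' @param n number of samples (classes drawn uniformly).
#' @param size square image side.
#' @param seed RNG seed.
#' @param noise_sigma additive Gaussian noise level.
#' @param jitter maximum absolute glyph offset in pixels.
#' @return list of \code{list(image = size x size x 1 array, label = 0..9)}.
#' @export
synth_digits <- function(n = 1000, size = 16, seed = 1, noise_sigma = 0.15,
                         jitter = 2) {
  set.seed(seed)
  out <- vector("list", n)
  gw <- size * 0.45
  gh <- size * 0.7
  t <- 0.3
  for (i in seq_len(n)) {
    lab <- sample(0:9, 1)
    ox <- (size - gw) / 2 + stats::runif(1, -jitter, jitter)
    oy <- (size - gh) / 2 + stats::runif(1, -jitter, jitter)
    img <- matrix(0, size, size)
    r <- rep.int(seq_len(size), size)
    c <- rep(seq_len(size), each = size)
    for (seg in .seven_segments[[as.character(lab)]]) {
      rc <- .segment_rect(seg, t)
      x0 <- ox + rc[1] * gw; x1 <- ox + rc[2] * gw
      y0 <- oy + rc[3] * gh; y1 <- oy + rc[4] * gh
      hit <- c >= x0 & c <= x1 & r >= y0 & r <= y1
      img[hit] <- 1
    }
    img <- img * stats::runif(1, 0.7, 1) +
      matrix(stats::rnorm(size * size, sd = noise_sigma), size, size)
    img <- pmin(pmax(img, 0), 1)
    out[[i]] <- list(image = array(img, c(size, size, 1)), label = lab)
  }
  out
}
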