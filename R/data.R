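#' Labelled wound image
#'
#' An RGB image in [0, 1] paired with a per-pixel class mask: 0 marks the burn
#' area, 1 everything else (unburned skin, clothing, background).
#'
#' @param image H x W x 3 array with values in [0, 1].
#' @param mask H x W integer matrix with values in \{0, 1\}.
#' @param id identifier string.
#' @return An object of class \code{labeled_image}.
#' @export
labeled_image <- function(image, mask, id = "img") {
  stopifnot(length(dim(image)) == 3, is.matrix(mask))
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask spatial dimensions differ")
  if (any(mask != 0 & mask != 1))
    stop("mask values must be 0 (burn) or 1 (non-burn)")
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "labeled_image")
}

.read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package")
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3) img <- aperm(img, c(2, 1, 3)) else img <- t(img)
  } else stop("unsupported image format: ", path)
  img
}

.read_mask_file <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  v <- round(m * 255)
  if (all(v %in% c(0, 255))) v <- v / 255
  if (any(!v %in% c(0, 1)))
    stop("mask is not binary: ", path)
  matrix(as.integer(v), nrow(m), ncol(m))
}

#' Load a paired image/mask dataset
#'
#' Expects \code{dir/images/*.png|jpg} and \code{dir/masks/*.png} matched by
#' file base name. Masks are validated to be binary.
#'
#' @param dir dataset directory.
#' @return list of \code{\link{labeled_image}} objects (possibly empty).
#' @export
load_dataset <- function(dir) {
  img_dir <- file.path(dir, "images")
  mask_dir <- file.path(dir, "masks")
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  if (length(imgs) == 0) return(list())
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    id <- tools::file_path_sans_ext(imgs[i])
    mask_path <- file.path(mask_dir, paste0(id, ".png"))
    if (!file.exists(mask_path))
      stop("no mask found for image: ", imgs[i])
    img <- .read_image_file(file.path(img_dir, imgs[i]))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    out[[i]] <- labeled_image(img, .read_mask_file(mask_path), id)
  }
  out
}

#' Write a dataset to the standard layout
#'
#' Writes \code{images/<id>.png}, single-channel \code{masks/<id>.png} (pixel
#' values 0/1) and a \code{manifest.csv} with ids and split labels.
#'
#' @param items list of \code{\link{labeled_image}}.
#' @param dir output directory (created).
#' @param split optional character vector of split labels per item.
#' @return \code{dir}, invisibly.
#' @export
save_dataset <- function(items, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (it in items) {
    png::writePNG(it$image, file.path(dir, "images", paste0(it$id, ".png")))
    png::writePNG(it$mask / 255, file.path(dir, "masks", paste0(it$id, ".png")))
  }
  ids <- vapply(items, function(it) it$id, character(1))
  if (is.null(split)) split <- rep("train", length(ids))
  utils::write.csv(data.frame(id = ids, split = split),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Augmentation policy
#'
#' The offline policy expands each image 20-fold: transposition (random flips,
#' translations within +/- \code{translation} pixels, rotations within
#' +/- \code{rotation} degrees) makes 5 copies including the original, and
#' each copy receives the 4 colour-jitter variants (brightness, contrast,
#' saturation, sharpness with factors drawn from their ranges; factor 1 is the
#' identity). Salt-and-pepper noise and a rectangular pixel mask corrupt the
#' images in place.
#'
#' @param translation maximum absolute translation in pixels.
#' @param rotation maximum absolute rotation in degrees.
#' @param transposition_copies copies produced by the transposition stage
#'   (including the original).
#' @param jitter_copies copies produced by the jitter stage.
#' @param brightness,contrast,saturation,sharpness factor ranges
#'   \code{c(min, max)}.
#' @param salt_pepper_prob probability that a pixel is forced to black or
#'   white (half each).
#' @param mask_prob probability of zeroing one random square patch.
#' @param mask_size side of the zeroed patch in pixels.
#' @param seed RNG seed for \code{\link{build_augmented_dataset}}.
#' @return An object of class \code{augment_policy}.
#' @export
augment_policy <- function(translation = 100, rotation = 90,
                           transposition_copies = 5, jitter_copies = 4,
                           brightness = c(0.5, 1.5), contrast = c(0.5, 1.5),
                           saturation = c(0, 2), sharpness = c(0, 2),
                           salt_pepper_prob = 0.01, mask_prob = 1,
                           mask_size = 16, seed = 1) {
  structure(list(translation = translation, rotation = rotation,
                 transposition_copies = transposition_copies,
                 jitter_copies = jitter_copies,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, sharpness = sharpness,
                 salt_pepper_prob = salt_pepper_prob, mask_prob = mask_prob,
                 mask_size = mask_size, seed = seed),
            class = "augment_policy")
}

# Inverse-mapped affine transform (flip -> rotate -> translate), nearest
# neighbour for image and mask alike so the mask value set is preserved;
# out-of-frame pixels fill with zeros.
.affine_item <- function(item, flip_h, flip_v, angle_deg, dx, dy) {
  d <- dim(item$image)
  H <- d[1]; W <- d[2]; C <- d[3]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- rep.int(seq_len(H), W)
  c <- rep(seq_len(W), each = H)
  # undo translation
  rr <- r - dy; cc2 <- c - dx
  # undo rotation about the centre
  th <- -angle_deg * pi / 180
  ry <- rr - cr; rx <- cc2 - cc
  sr <- cos(th) * ry - sin(th) * rx + cr
  sc <- sin(th) * ry + cos(th) * rx + cc
  # undo flips
  if (flip_h) sc <- W + 1 - sc
  if (flip_v) sr <- H + 1 - sr
  sr <- round(sr); sc <- round(sc)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  src <- (sc - 1) * H + sr
  imat <- matrix(item$image, H * W, C)
  out <- matrix(0, H * W, C)
  out[ok, ] <- imat[src[ok], ]
  mout <- integer(H * W)
  mv <- as.integer(item$mask)
  mout[ok] <- mv[src[ok]]
  labeled_image(array(out, d), matrix(mout, H, W), item$id)
}

#' Flip a labelled image
#'
#' @param item a \code{\link{labeled_image}}.
#' @param axis \code{"horizontal"} (left-right) or \code{"vertical"}.
#' @return the flipped \code{labeled_image}.
#' @export
flip_item <- function(item, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  .affine_item(item, axis == "horizontal", axis == "vertical", 0, 0, 0)
}

#' Transposition augmentation
#'
#' Returns the original plus \code{transposition_copies - 1} randomized
#' flip/translate/rotate copies; the mask is transformed identically with
#' nearest-neighbour resampling.
#'
#' @param item a \code{\link{labeled_image}}.
#' @param policy an \code{\link{augment_policy}}.
#' @return list of \code{labeled_image}s.
#' @export
augment_transposition <- function(item, policy = augment_policy()) {
  out <- vector("list", policy$transposition_copies)
  out[[1]] <- item
  for (i in seq_len(policy$transposition_copies - 1)) {
    out[[i + 1]] <- .affine_item(
      item,
      flip_h = stats::runif(1) < 0.5,
      flip_v = stats::runif(1) < 0.5,
      angle_deg = stats::runif(1, -policy$rotation, policy$rotation),
      dx = round(stats::runif(1, -policy$translation, policy$translation)),
      dy = round(stats::runif(1, -policy$translation, policy$translation)))
  }
  out
}

.luminance <- function(m3) {
  0.299 * m3[, 1] + 0.587 * m3[, 2] + 0.114 * m3[, 3]
}

# Local-mean smoothing with edge-aware normalisation (weights 1/5/1 box).
.smooth_matrix <- function(x, H, W) {
  kern <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1) / 13, 9, 1)
  ones <- matrix(1, H * W, 1)
  norm <- conv2d(ones, kern, 0, H, W, 3)
  out <- x
  for (ch in seq_len(ncol(x)))
    out[, ch] <- conv2d(x[, ch, drop = FALSE], kern, 0, H, W, 3) / norm
  out
}

# Single colour-jitter transform on an (H*W) x 3 matrix.
.jitter_one <- function(x, H, W, type, factor) {
  out <- switch(type,
    brightness = x * factor,
    contrast = {
      g <- mean(.luminance(x))
      g + factor * (x - g)
    },
    saturation = {
      L <- .luminance(x)
      L + factor * (x - L)
    },
    sharpness = {
      sm <- .smooth_matrix(x, H, W)
      sm + factor * (x - sm)
    },
    stop("unknown jitter type"))
  pmin(pmax(out, 0), 1)
}

# Random single jitter used per batch during training.
.jitter_matrix <- function(x, H, W, policy = augment_policy()) {
  type <- sample(c("brightness", "contrast", "saturation", "sharpness"), 1)
  rng <- policy[[type]]
  .jitter_one(x, H, W, type, stats::runif(1, rng[1], rng[2]))
}

#' Colour-jitter augmentation
#'
#' Produces one copy per jitter type (brightness, contrast, saturation,
#' sharpness), each with a factor drawn from the policy's range for that type;
#' factor 1 reproduces the original, factor 0 gives a black, flat-grey, or
#' black-and-white image for brightness/contrast/saturation. Masks are never
#' touched.
#'
#' @inheritParams augment_transposition
#' @param factors optional named numeric vector forcing the factors (used for
#'   deterministic checks).
#' @return list of \code{jitter_copies} \code{labeled_image}s.
#' @export
augment_jitter <- function(item, policy = augment_policy(), factors = NULL) {
  d <- dim(item$image)
  H <- d[1]; W <- d[2]
  x <- matrix(item$image, H * W, 3)
  types <- c("brightness", "contrast", "saturation", "sharpness")[
    seq_len(policy$jitter_copies)]
  out <- vector("list", length(types))
  for (i in seq_along(types)) {
    ty <- types[i]
    f <- if (!is.null(factors)) factors[[ty]]
         else stats::runif(1, policy[[ty]][1], policy[[ty]][2])
    y <- .jitter_one(x, H, W, ty, f)
    out[[i]] <- labeled_image(array(y, d), item$mask, item$id)
  }
  out
}

#' Noise augmentation
#'
#' In-place corruption: every pixel is independently forced to black or white
#' with probability \code{salt_pepper_prob/2} each, and with probability
#' \code{mask_prob} one random \code{mask_size}-square patch is zeroed. The
#' label mask is untouched.
#'
#' @inheritParams augment_transposition
#' @return the corrupted \code{labeled_image}.
#' @export
augment_noise <- function(item, policy = augment_policy()) {
  d <- dim(item$image)
  H <- d[1]; W <- d[2]
  x <- matrix(item$image, H * W, 3)
  u <- stats::runif(H * W)
  x[u < policy$salt_pepper_prob / 2, ] <- 0
  x[u >= policy$salt_pepper_prob / 2 & u < policy$salt_pepper_prob, ] <- 1
  if (policy$mask_prob > 0 && stats::runif(1) < policy$mask_prob) {
    ms <- min(policy$mask_size, H, W)
    r0 <- sample.int(H - ms + 1, 1)
    c0 <- sample.int(W - ms + 1, 1)
    rows <- as.vector(outer(r0:(r0 + ms - 1), (c0:(c0 + ms - 1) - 1) * H, `+`))
    x[rows, ] <- 0
  }
  labeled_image(array(x, d), item$mask, item$id)
}

#' Build the offline-augmented dataset
#'
#' Applies transposition (x5) then colour jitter (x4) compositionally and
#' noise in place, expanding the dataset exactly
#' \code{transposition_copies * jitter_copies}-fold (20 by default).
#' Deterministic under the policy seed.
#'
#' @param items list of \code{\link{labeled_image}}.
#' @param policy an \code{\link{augment_policy}}.
#' @return list of augmented \code{labeled_image}s.
#' @export
build_augmented_dataset <- function(items, policy = augment_policy()) {
  set.seed(policy$seed)
  out <- vector("list", length(items) * policy$transposition_copies *
                  policy$jitter_copies)
  k <- 0
  for (it in items) {
    for (tr in augment_transposition(it, policy)) {
      for (jt in augment_jitter(tr, policy)) {
        k <- k + 1
        noisy <- augment_noise(jt, policy)
        noisy$id <- paste0(it$id, "_aug", k)
        out[[k]] <- noisy
      }
    }
  }
  out
}

# Bilinear resize of a labelled image (mask nearest-neighbour).
.resize_item <- function(item, Hout, Wout) {
  d <- dim(item$image)
  x <- matrix(item$image, d[1] * d[2], d[3])
  y <- resize_bilinear(x, d[1], d[2], Hout, Wout)
  y <- pmin(pmax(y, 0), 1)
  labeled_image(array(y, c(Hout, Wout, d[3])),
                resize_nearest(item$mask, Hout, Wout), item$id)
}

#' Crop a large annotated image into balanced tiles
#'
#' Slides a square window over the image, scores each position by the balance
#' of burn/non-burn pixels (the minimum class share), and greedily keeps the
#' best-scoring windows subject to pairwise disjointness; when no window
#' contains both classes it falls back to a regular non-overlapping grid.
#' Every kept crop is resized to \code{target} x \code{target} (bilinear for
#' the image, nearest-neighbour for the mask).
#'
#' @param item a \code{\link{labeled_image}} larger than \code{target}.
#' @param target output side length.
#' @param crop_size window side in source pixels; default half the smaller
#'   image side.
#' @param stride sliding stride; default half the window.
#' @return list of \code{labeled_image}s of size \code{target} x \code{target}.
#' @export
crop_and_resize <- function(item, target = 256, crop_size = NULL,
                            stride = NULL) {
  d <- dim(item$image)
  H <- d[1]; W <- d[2]
  if (is.null(crop_size)) crop_size <- max(target, min(H, W) %/% 2)
  if (H < crop_size || W < crop_size)
    return(list(.resize_item(item, target, target)))
  if (is.null(stride)) stride <- max(1L, crop_size %/% 2L)

  burn <- item$mask == 0
  S <- matrix(0, H + 1, W + 1)          # integral image of burn pixels
  S[-1, -1] <- t(apply(apply(burn, 2, cumsum), 1, cumsum))
  win_sum <- function(r, c) {
    S[r + crop_size, c + crop_size] - S[r, c + crop_size] -
      S[r + crop_size, c] + S[r, c]
  }
  rs <- unique(c(seq(1, H - crop_size + 1, by = stride), H - crop_size + 1))
  cs <- unique(c(seq(1, W - crop_size + 1, by = stride), W - crop_size + 1))
  cand <- expand.grid(r = rs, c = cs)
  npix <- crop_size^2
  share0 <- mapply(win_sum, cand$r, cand$c) / npix
  cand$score <- pmin(share0, 1 - share0)

  chosen <- list()
  if (max(cand$score) > 0) {
    cand <- cand[order(-cand$score), ]
    for (i in seq_len(nrow(cand))) {
      if (cand$score[i] <= 0) break
      r <- cand$r[i]; c <- cand$c[i]
      clash <- any(vapply(chosen, function(ch)
        abs(ch$r - r) < crop_size && abs(ch$c - c) < crop_size, logical(1)))
      if (!clash) chosen[[length(chosen) + 1]] <- list(r = r, c = c)
    }
  }
  if (length(chosen) == 0) {            # single-class image: regular grid
    for (r in seq(1, H - crop_size + 1, by = crop_size))
      for (c in seq(1, W - crop_size + 1, by = crop_size))
        chosen[[length(chosen) + 1]] <- list(r = r, c = c)
  }
  lapply(seq_along(chosen), function(i) {
    ch <- chosen[[i]]
    sub <- labeled_image(
      item$image[ch$r:(ch$r + crop_size - 1), ch$c:(ch$c + crop_size - 1), ,
                 drop = FALSE],
      item$mask[ch$r:(ch$r + crop_size - 1), ch$c:(ch$c + crop_size - 1)],
      paste0(item$id, "_crop", i))
    out <- .resize_item(sub, target, target)
    attr(out, "origin") <- c(ch$r, ch$c, crop_size)
    out
  })
}
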