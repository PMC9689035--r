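test_that("labeled_image validates its fields", {
  img <- array(0.5, c(8, 8, 3))
  mk <- matrix(1L, 8, 8)
  it <- labeled_image(img, mk, "a")
  expect_s3_class(it, "labeled_image")
  expect_error(labeled_image(array(0.5, c(8, 8, 3)), matrix(2, 8, 8)))
  expect_error(labeled_image(array(0.5, c(8, 8, 3)), matrix(1, 4, 8)))
})

test_that("the offline policy expands every image exactly 20-fold", {
  set.seed(50)
  items <- list(rand_item(16, 16, 1), rand_item(16, 16, 2))
  pol <- augment_policy(translation = 4, mask_size = 4)
  aug <- build_augmented_dataset(items, pol)
  expect_length(aug, 40)                       # 2 images x 5 x 4
  expect_true(all(vapply(aug, function(a) all(a$mask %in% c(0, 1)),
                         logical(1))))
  expect_true(all(vapply(aug, function(a)
    min(a$image) >= 0 && max(a$image) <= 1, logical(1))))
  # fully deterministic under the policy seed
  aug2 <- build_augmented_dataset(items, pol)
  expect_identical(aug, aug2)
})

test_that("flips are involutions and preserve the mask pairing", {
  it <- rand_item(12, 10, 3)
  for (ax in c("horizontal", "vertical")) {
    f2 <- flip_item(flip_item(it, ax), ax)
    expect_equal(f2$image, it$image)
    expect_equal(f2$mask, it$mask)
  }
  fh <- flip_item(it, "horizontal")
  expect_equal(fh$image[1, , ], it$image[1, rev(seq_len(10)), ])
  expect_equal(fh$mask, it$mask[, rev(seq_len(10))])
})

test_that("colour jitter follows the factor semantics", {
  it <- rand_item(8, 8, 4)
  # one copy per type with forced factors (0/0/0/1)
  js <- augment_jitter(it, factors = list(brightness = 0, contrast = 0,
                                          saturation = 0, sharpness = 1))
  expect_length(js, 4)
  # brightness 0 -> black
  expect_equal(max(js[[1]]$image), 0)
  # contrast 0 -> constant mean-luminance image
  expect_lt(max(js[[2]]$image) - min(js[[2]]$image), 1e-10)
  # saturation 0 -> greyscale (channels equal)
  expect_equal(js[[3]]$image[, , 1], js[[3]]$image[, , 2], tolerance = 1e-12)
  expect_equal(js[[3]]$image[, , 2], js[[3]]$image[, , 3], tolerance = 1e-12)
  # sharpness 1 -> identity
  expect_equal(js[[4]]$image, it$image, tolerance = 1e-12)
  # factor 1 is the identity for every type
  j1 <- augment_jitter(it, factors = list(brightness = 1, contrast = 1,
                                          saturation = 1, sharpness = 1))
  for (j in j1) expect_equal(j$image, it$image, tolerance = 1e-12)
  # jitter never touches the mask
  expect_equal(js[[2]]$mask, it$mask)
})

test_that("noise corruption follows the policy knobs", {
  it <- rand_item(32, 32, 5)
  none <- augment_noise(it, augment_policy(salt_pepper_prob = 0, mask_prob = 0))
  expect_equal(none$image, it$image)
  pol <- augment_policy(salt_pepper_prob = 0.2, mask_prob = 1, mask_size = 8,
                        seed = 3)
  set.seed(3)
  nz <- augment_noise(it, pol)
  expect_true(min(nz$image) >= 0 && max(nz$image) <= 1)
  # a zeroed 8x8 patch exists: some row band sums to zero across channels
  sums <- apply(nz$image, c(1, 2), sum)
  expect_true(any(sums == 0))
  # salt-and-pepper flipped a nontrivial share of pixels to exactly 0 or 1
  flipped <- mean(nz$image == 0 | nz$image == 1)
  expect_gt(flipped, 0.05)
})

test_that("datasets round-trip through the standard directory layout", {
  set.seed(51)
  items <- list(rand_item(16, 16, 6), rand_item(16, 16, 7))
  dir <- file.path(tempfile("ds"))
  save_dataset(items, dir, split = c("train", "test"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_dataset(dir)
  expect_length(back, 2)
  ids <- vapply(back, function(b) b$id, character(1))
  for (i in seq_along(items)) {
    j <- match(items[[i]]$id, ids)
    expect_equal(back[[j]]$mask, items[[i]]$mask)
    expect_equal(back[[j]]$image, items[[i]]$image, tolerance = 1 / 254)
  }
})

test_that("loading reports missing masks and rejects non-binary masks", {
  dir <- tempfile("bad")
  dir.create(file.path(dir, "images"), recursive = TRUE)
  dir.create(file.path(dir, "masks"), recursive = TRUE)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "images", "a.png"))
  expect_error(load_dataset(dir), "no mask")
  png::writePNG(matrix(0.37, 8, 8), file.path(dir, "masks", "a.png"))
  expect_error(load_dataset(dir), "binary")
})

test_that("crop_and_resize emits fixed-size crops covering the lesion", {
  set.seed(52)
  mk <- matrix(1L, 64, 64)
  mk[20:35, 24:39] <- 0L
  it <- labeled_image(array(runif(64 * 64 * 3), c(64, 64, 3)), mk, "c")
  crops <- crop_and_resize(it, target = 32, crop_size = 32)
  expect_gt(length(crops), 0)
  for (cr in crops) {
    expect_equal(dim(cr$image), c(32, 32, 3))
    expect_equal(dim(cr$mask), c(32, 32))
    expect_true(all(cr$mask %in% c(0, 1)))
    expect_false(is.null(attr(cr, "origin")))
  }
  # at least one crop contains lesion pixels
  expect_true(any(vapply(crops, function(cr) any(cr$mask == 0), logical(1))))
})

test_that("rotations preserve binary masks and image bounds", {
  it <- rand_item(20, 20, 8)
  set.seed(8)
  pol <- augment_policy(translation = 2, rotation = 90)
  for (k in 1:5) {
    tr <- augment_transposition(it, pol)
    for (x in tr) {
      expect_true(all(x$mask %in% c(0, 1)))
      expect_true(min(x$image) >= 0 && max(x$image) <= 1)
      expect_equal(dim(x$image), dim(it$image))
    }
  }
})
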