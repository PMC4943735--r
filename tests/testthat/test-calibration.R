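test_that("PNG write/read round-trips within 8-bit quantization", {
  img <- random_image(40, 52, seed = 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, path)
  back <- load_image(path)
  expect_equal(back$height, 40)
  expect_equal(back$width, 52)
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)
})

test_that("grayscale sources are replicated to three identical channels", {
  m <- matrix(seq(0, 1, length.out = 40 * 40), 40, 40)
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(m)), path, type = "png")
  img <- load_image(path)
  expect_equal(img$pixels[, , 1], img$pixels[, , 2])
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])
})

test_that("load_image rejects missing files and undersized images", {
  expect_error(load_image(file.path(tempdir(), "nope.png")), "does not exist")
  tiny <- array(0.5, dim = c(8, 8, 3))
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(aperm(tiny, c(2, 1, 3)), colormode = "Color"),
                      path, type = "png")
  expect_error(load_image(path), "too small")
})

test_that("white calibration applies the per-channel gain exactly", {
  # uniform mid-gray with target white: gains (2,2,2), output all 1
  img <- uniform_image(c(0.5, 0.5, 0.5))
  cal <- calibrate_white(img, ref_region(0, 0, 8, 8))
  expect_equal(cal$gains, c(2, 2, 2))
  expect_true(all(cal$pixels == 1))

  # a reference already at the target leaves the image unchanged
  img2 <- uniform_image(c(0.8, 0.6, 0.4))
  cal2 <- calibrate_white(img2, ref_region(0, 0, 8, 8),
                          reference_white = c(0.8, 0.6, 0.4))
  expect_equal(cal2$gains, c(1, 1, 1))
  expect_equal(cal2$pixels, img2$pixels)
})

test_that("post-calibration reference mean hits the target and calibration is idempotent", {
  # bright image with a sub-unit target: all gains < 1, so no pixel clips
  # and the post-calibration reference mean is exact
  px <- 0.6 + 0.3 * pattsig:::with_seed(9, array(runif(48 * 48 * 3), dim = c(48, 48, 3)))
  img <- as_calibrated_image(px)
  ref <- ref_region(4, 4, 16, 16)
  white <- c(0.6, 0.6, 0.6)
  cal <- calibrate_white(img, ref, white)
  means <- vapply(1:3, function(ch) mean(cal$pixels[5:16, 5:16, ch]), numeric(1))
  expect_equal(means, white, tolerance = 1e-6)
  cal2 <- calibrate_white(cal, ref, white)
  expect_equal(cal2$pixels, cal$pixels, tolerance = 1e-6)
  expect_equal(cal2$gains, c(1, 1, 1), tolerance = 1e-6)
})

test_that("degenerate (all-zero) reference regions are rejected", {
  px <- array(0.5, dim = c(48, 48, 3))
  px[1:8, 1:8, ] <- 0
  img <- new_raw_image(px)
  expect_error(calibrate_white(img, ref_region(0, 0, 8, 8)), "degenerate")
  expect_error(calibrate_white(img, ref_region(0, 0, 80, 8)), "outside")
})

test_that("cropping selects the half-open box and preserves gains", {
  img <- random_image(48, 48, seed = 2)
  cal <- calibrate_white(img, ref_region(0, 0, 8, 8), c(0.9, 0.9, 0.9))
  full <- crop_body(cal, crop_box(0, 0, 48, 48))
  expect_equal(full$pixels, cal$pixels)
  sub <- crop_body(cal, crop_box(5, 7, 15, 17))
  expect_equal(dim(sub$pixels), c(10L, 10L, 3L))
  expect_equal(sub$pixels[1, 1, ], cal$pixels[6, 8, ])
  expect_equal(sub$gains, cal$gains)
  expect_error(crop_body(cal, crop_box(40, 40, 60, 60)), "outside")
  expect_error(crop_box(5, 5, 5, 10), "non-empty")
})

test_that("nested crops equal the one-shot composed crop exactly", {
  cal <- as_calibrated_image(random_image(64, 64, seed = 5)$pixels)
  a <- crop_box(4, 6, 52, 60)
  b <- crop_box(3, 2, 33, 40)
  nested <- crop_body(crop_body(cal, a), b)
  oneshot <- crop_body(cal, compose_crops(a, b))
  expect_identical(nested$pixels, oneshot$pixels)
})

test_that("luminance uses the BT.601 weights and stays within channel bounds", {
  expect_equal(max(abs(to_luminance(uniform_image(c(1, 1, 1))) - 1)), 0,
               tolerance = 1e-12)
  expect_equal(unique(as.numeric(to_luminance(uniform_image(c(1, 0, 0))))), 0.299)
  img <- random_image(32, 32, seed = 4)
  L <- to_luminance(img)
  lo <- pmin(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  hi <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3])
  expect_true(all(L >= lo - 1e-12 & L <= hi + 1e-12))
})

test_that("pixel spans convert to physical lengths", {
  expect_equal(pixels_to_length(100, 10), 10)
  expect_equal(pixels_to_length(0.5, 1), 0.5)
  expect_error(pixels_to_length(-1, 10), "positive")
  expect_error(pixels_to_length(10, 0), "positive")
})

test_that("scale recovered from a drawn ruler measures a known span within 1%", {
  # ruler: dark ticks every 12 px on a light strip; 12 px per cm
  w <- 200
  px <- array(0.9, dim = c(40, w, 3))
  tick_cols <- seq(10, w - 10, by = 12)
  for (tc in tick_cols) px[, tc, ] <- 0.05
  img <- as_calibrated_image(px)
  prof <- colMeans(to_luminance(img))
  found <- which(prof < 0.5)
  scale_px_per_cm <- mean(diff(found))
  # a span drawn to cover 96 px = 8 cm
  expect_lt(abs(pixels_to_length(96, scale_px_per_cm) - 8), 0.08)
})

test_that("area-average resize preserves constants and equals block means", {
  flat <- uniform_image(c(0.3, 0.6, 0.9), 128, 128)
  small <- resize_max_side(flat, 64)
  expect_equal(small$height, 64)
  expect_true(max(abs(sweep(small$pixels, 3, c(0.3, 0.6, 0.9)))) < 1e-12)

  img <- random_image(128, 128, seed = 6)
  half <- resize_max_side(img, 64)
  # integer 2x reduction: each output pixel is the mean of a 2x2 block
  blocks <- img$pixels[seq(1, 127, 2), seq(1, 127, 2), 1] +
    img$pixels[seq(2, 128, 2), seq(1, 127, 2), 1] +
    img$pixels[seq(1, 127, 2), seq(2, 128, 2), 1] +
    img$pixels[seq(2, 128, 2), seq(2, 128, 2), 1]
  expect_equal(half$pixels[, , 1], blocks / 4, tolerance = 1e-12)
  # images already within the limit are untouched
  expect_identical(resize_max_side(img, 256)$pixels, img$pixels)
})
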