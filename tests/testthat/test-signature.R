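make_corpus <- function(n = 3, h = 48, w = 48, seed = 1) {
  lapply(seq_len(n), function(i)
    compute_c1(list(luminance = to_luminance(random_image(h, w, seed + i))),
               small_bank()))
}

test_that("templates are split equally among size classes, deterministically", {
  corpus <- make_corpus()
  ts <- sample_templates(corpus, n_templates = 8, size_classes = c(2, 3, 4, 5),
                         seed = 42)
  expect_equal(vapply(ts$patches, nrow, integer(1)), rep(2L, 4))
  expect_equal(nrow(ts$sources), 8L)
  ts2 <- sample_templates(corpus, n_templates = 8, size_classes = c(2, 3, 4, 5),
                          seed = 42)
  expect_identical(ts$patches, ts2$patches)
  expect_identical(ts$sources, ts2$sources)
  # n_templates = k gives one template per class
  ts1 <- sample_templates(corpus, n_templates = 4, size_classes = c(2, 3, 4, 5),
                          seed = 1)
  expect_equal(vapply(ts1$patches, nrow, integer(1)), rep(1L, 4))
  expect_error(sample_templates(corpus, 6, c(2, 3, 4, 5), 1), "multiple")
  expect_error(sample_templates(corpus, 4, c(2, 3, 4, 99), 1), "not fit")
})

test_that("an image containing a template's source location self-matches at 1", {
  corpus <- make_corpus()
  ts <- sample_templates(corpus, n_templates = 4, size_classes = c(2, 3, 4, 5),
                         seed = 3)
  for (j in seq_len(nrow(ts$sources))) {
    src_img <- ts$sources$image[j]
    sig <- compute_signature(corpus[[src_img]], ts)
    expect_equal(sig$values[j], 1.0, tolerance = 1e-12)
  }
})

test_that("signature values lie in (0, 1] and follow the closed form on zero stacks", {
  corpus <- make_corpus()
  ts <- sample_templates(corpus, 4, c(2, 3, 4, 5), seed = 5)
  zero <- compute_c1(list(luminance = matrix(0, 48, 48)), small_bank())
  sig <- compute_signature(zero, ts)
  expect_true(all(sig$values > 0 & sig$values <= 1))
  per <- 1L
  for (ci in 1:4) {
    L <- ncol(ts$patches[[ci]])
    expected <- exp(-sum(ts$patches[[ci]][1, ]^2) / (2 * L))
    expect_equal(sig$values[(ci - 1) * per + 1], expected, tolerance = 1e-12)
    expect_lt(sig$values[(ci - 1) * per + 1], 1)
  }
})

test_that("max-similarity pooling equals an exhaustive location scan", {
  corpus <- make_corpus(n = 2)
  ts <- sample_templates(corpus, 8, c(2, 3), seed = 9)
  target <- corpus[[1]]
  sig <- compute_signature(target, ts)
  # independent oracle: nested loops over every band, location and slice
  oracle <- numeric(8)
  sizes <- rep(ts$size_classes, each = 4)
  for (j in 1:8) {
    ci <- (j - 1) %/% 4 + 1
    s <- ts$size_classes[ci]
    tmpl <- ts$patches[[ci]][(j - 1) %% 4 + 1, ]
    best <- -Inf
    for (b in seq_along(target$band_defs)) {
      maps <- lapply(seq_len(target$n_orientations), function(o)
        target$bands$luminance[[b]][, , o])
      h <- nrow(maps[[1]]); w <- ncol(maps[[1]])
      if (h < s || w < s) next
      for (r in 1:(h - s + 1)) for (cc in 1:(w - s + 1)) {
        patch <- unlist(lapply(maps, function(m) m[r:(r + s - 1), cc:(cc + s - 1)]))
        d2 <- sum((patch - tmpl)^2)
        best <- max(best, exp(-d2 / (2 * length(tmpl))))
      }
    }
    oracle[j] <- best
  }
  expect_equal(sig$values, oracle, tolerance = 1e-12)
})

test_that("grayscale templates refuse color stacks and vice versa", {
  gray <- make_corpus(n = 2)
  img <- random_image(48, 48, seed = 11)
  colstack <- compute_c1(c(list(luminance = to_luminance(img)),
                           compute_opponent_channels(img)$maps), small_bank())
  ts_gray <- sample_templates(gray, 4, c(2, 3, 4, 5), seed = 1)
  expect_error(compute_signature(colstack, ts_gray), "mismatch")
})

test_that("the batch driver returns an n x T matrix in input order", {
  imgs <- lapply(1:4, function(i) random_image(64, 64, seed = 20 + i))
  run <- build_signature_matrix(imgs, mode = "grayscale", bank = small_bank(),
                                n_templates = 8, size_classes = c(2, 3, 4, 5),
                                seed = 2)
  expect_equal(dim(run$signatures), c(4L, 8L))
  expect_true(all(run$signatures > 0 & run$signatures <= 1))
  run2 <- build_signature_matrix(imgs, mode = "grayscale", bank = small_bank(),
                                 n_templates = 8, size_classes = c(2, 3, 4, 5),
                                 seed = 2)
  expect_identical(run$signatures, run2$signatures)
  expect_error(build_signature_matrix(imgs[1], mode = "grayscale"), "at least 2")
})

test_that("the grayscale pathway ignores constant-luminance hue rotation; color does not", {
  specs <- matched_luminance_specs()
  # pair i of each class shares its seed, so geometry is identical within
  # a pair and only the (luminance-matched) hues differ
  gens <- c(lapply(1:2, function(i) generate_pattern_image(specs$g, c(72, 72), seed = 30 + i)),
            lapply(1:2, function(i) generate_pattern_image(specs$r, c(72, 72), seed = 30 + i)))
  imgs <- lapply(gens, function(g) crop_body(calibrate_white(g$image, g$ref), g$body))
  g1 <- to_luminance(imgs[[1]]); g2 <- to_luminance(imgs[[3]])
  expect_lt(max(abs(g1 - g2)), 1e-9)
  gray <- build_signature_matrix(imgs, mode = "grayscale", bank = small_bank(),
                                 n_templates = 8, size_classes = c(2, 3, 4, 5),
                                 seed = 5)
  expect_lt(max(abs(gray$signatures[1, ] - gray$signatures[3, ])), 1e-6)
  expect_lt(max(abs(gray$signatures[2, ] - gray$signatures[4, ])), 1e-6)
  col <- build_signature_matrix(imgs, mode = "color", bank = small_bank(),
                                n_templates = 8, size_classes = c(2, 3, 4, 5),
                                seed = 5)
  expect_gt(max(abs(col$signatures[1, ] - col$signatures[3, ])), 1e-4)
})

test_that("signature CSV round-trips", {
  m <- matrix(runif(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signatures_csv(m, path)
  back <- read_signatures_csv(path)
  expect_equal(unname(back), unname(m), tolerance = 1e-12)
  expect_equal(rownames(back), rownames(m))
})
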