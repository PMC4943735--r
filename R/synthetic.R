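# Synthetic data: pattern-class body images (elliptical body with base
# color, stripes, blotches, noise, plus an in-frame white strip so the
# calibration stage is exercised end-to-end) and capture-metadata tables
# in which the probability of brown body color follows a logistic model
# in month and snout-vent length. These stand in for field photographs
# and capture records so every pipeline stage is testable.

#' Describe a synthetic pattern class
#'
#' A generative description of one body-pattern class along the three
#' axes that define pattern categories — base color, stripes, and
#' blotches — plus overall brightness and within-class noise.
#'
#' @param class_name Label of the class.
#' @param base_color Length-3 RGB reflectance in \[0, 1\].
#' @param stripe Optional list: `count` (integer), `orientation`
#'   (`"vertical"` or `"horizontal"`), `width_frac` (stripe width as a
#'   fraction of the body extent, in (0, 1)), `color` (RGB).
#' @param blotches Optional list: `count`, `radius_range` (two fractions
#'   of the body minor semi-axis, in (0, 1)), `color` (RGB).
#' @param body_aspect Width/height ratio of the elliptical body
#'   (default 1.8, an elongated laterally viewed body).
#' @param noise List: `hue_sd` (per-image color-cast jitter),
#'   `placement_sd` (stripe/blotch placement jitter, fraction of the
#'   body extent), `pixel_sd` (iid pixel noise). All >= 0.
#' @param brightness Multiplier applied to all body colors (default 1;
#'   > 1 gives a "brighter version" of the same pattern).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(class_name, base_color,
                         stripe = NULL, blotches = NULL,
                         body_aspect = 1.8,
                         noise = list(hue_sd = 0.02, placement_sd = 0.02,
                                      pixel_sd = 0.02),
                         brightness = 1) {
  check_rgb <- function(x, what) {
    if (!is.numeric(x) || length(x) != 3L || any(x < 0) || any(x > 1))
      stop_validation(what, " must be 3 values in [0, 1]")
  }
  check_rgb(base_color, "base_color")
  if (!is.null(stripe)) {
    if (!all(c("count", "orientation", "width_frac", "color") %in% names(stripe)))
      stop_validation("stripe needs count, orientation, width_frac, color")
    if (!stripe$orientation %in% c("vertical", "horizontal"))
      stop_validation("stripe orientation must be vertical or horizontal")
    if (stripe$width_frac <= 0 || stripe$width_frac >= 1)
      stop_validation("stripe width_frac must lie in (0, 1)")
    check_rgb(stripe$color, "stripe color")
  }
  if (!is.null(blotches)) {
    if (!all(c("count", "radius_range", "color") %in% names(blotches)))
      stop_validation("blotches need count, radius_range, color")
    rr <- blotches$radius_range
    if (length(rr) != 2L || any(rr <= 0) || any(rr >= 1) || rr[1] > rr[2])
      stop_validation("blotch radius_range must be two increasing fractions in (0, 1) ",
                      "of the body minor semi-axis (a blotch may not exceed the body)")
    check_rgb(blotches$color, "blotch color")
  }
  ns <- noise
  if (!all(c("hue_sd", "placement_sd", "pixel_sd") %in% names(ns)) ||
      any(unlist(ns[c("hue_sd", "placement_sd", "pixel_sd")]) < 0))
    stop_validation("noise needs non-negative hue_sd, placement_sd, pixel_sd")
  if (!is_scalar_number(body_aspect) || body_aspect < 1)
    stop_validation("body_aspect must be >= 1")
  if (!is_scalar_number(brightness) || brightness <= 0)
    stop_validation("brightness must be > 0")
  structure(
    list(class_name = class_name, base_color = base_color, stripe = stripe,
         blotches = blotches, body_aspect = body_aspect, noise = ns,
         brightness = brightness),
    class = "pattern_spec")
}

#' Render one synthetic body image
#'
#' Draws an elliptical body of the spec's base color on a neutral
#' background, adds stripes and blotches with placement jitter, a
#' per-image color-cast (hue jitter), iid pixel noise, and a white
#' reference strip along the top edge. The whole frame is multiplied by
#' an illumination factor < 1, so recovering the spec's reflectance
#' colors requires white-standard calibration against the strip —
#' exercising the calibration stage end-to-end. Deterministic per seed.
#'
#' @param spec A [pattern_spec()].
#' @param size `c(H, W)` in pixels (default `c(128, 128)`).
#' @param seed Integer seed.
#' @param illumination Scalar in (0, 1\] multiplying the whole frame
#'   (default 0.85).
#' @param strip_frac Height of the white strip as a fraction of H.
#' @return A list: `image` (a `raw_image`), `ref` (a [ref_region()]
#'   covering the white strip), `body` (a [crop_box()] covering the body
#'   extent below the strip), `spec`, `seed`.
#' @export
generate_pattern_image <- function(spec, size = c(128L, 128L), seed = 1L,
                                   illumination = 0.85, strip_frac = 0.08) {
  if (!inherits(spec, "pattern_spec")) stop_validation("spec must be a pattern_spec")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 48L || W < 48L) stop_validation("size must be at least 48 x 48")
  if (!is_scalar_number(illumination) || illumination <= 0 || illumination > 1)
    stop_validation("illumination must lie in (0, 1]")
  strip <- max(6L, round(strip_frac * H))
  body_h <- H - strip - 2L
  cy <- strip + 2L + body_h / 2     # body center, 1-based rows
  cx <- (W + 1) / 2
  a <- 0.46 * W                      # column semi-axis
  b <- min(a / spec$body_aspect, 0.46 * body_h)
  with_seed(seed, {
    px <- array(rep(c(0.5, 0.5, 0.5), each = H * W), dim = c(H, W, 3L))
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    body <- ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
    cast <- stats::rnorm(3L, 0, spec$noise$hue_sd)
    paint <- function(mask, color) {
      col3 <- pmin(pmax(color * spec$brightness + cast, 0), 1)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[mask] <- col3[ch]
        px[, , ch] <<- plane
      }
    }
    paint(body, spec$base_color)
    if (!is.null(spec$stripe) && spec$stripe$count >= 1L) {
      st <- spec$stripe
      for (i in seq_len(st$count)) {
        frac <- i / (st$count + 1)
        if (st$orientation == "vertical") {
          center <- cx - a + 2 * a * frac + stats::rnorm(1, 0, spec$noise$placement_sd * W)
          half <- st$width_frac * a
          mask <- body & abs(cols - center) <= half
        } else {
          center <- cy - b + 2 * b * frac + stats::rnorm(1, 0, spec$noise$placement_sd * H)
          half <- st$width_frac * b
          mask <- body & abs(rows - center) <= half
        }
        paint(mask, st$color)
      }
    }
    if (!is.null(spec$blotches) && spec$blotches$count >= 1L) {
      bl <- spec$blotches
      for (i in seq_len(bl$count)) {
        th <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.7
        bcy <- cy + rad * b * sin(th) + stats::rnorm(1, 0, spec$noise$placement_sd * H)
        bcx <- cx + rad * a * cos(th) + stats::rnorm(1, 0, spec$noise$placement_sd * W)
        r <- stats::runif(1, bl$radius_range[1], bl$radius_range[2]) * b
        mask <- body & ((cols - bcx)^2 + (rows - bcy)^2 <= r^2)
        paint(mask, bl$color)
      }
    }
    for (ch in 1:3) px[1:strip, , ch] <- 1   # white reference strip
    px <- px * illumination
    if (spec$noise$pixel_sd > 0)
      px <- px + stats::rnorm(length(px), 0, spec$noise$pixel_sd)
    px <- pmin(pmax(px, 0), 1)
    list(image = new_raw_image(px, source_path = paste0("<synthetic:", spec$class_name, ">")),
         ref = ref_region(0L, 0L, strip, W),
         body = crop_box(strip + 2L, 0L, H, W),
         spec = spec, seed = seed)
  })
}

# Canonical numeric parameterization of a pattern_spec, used to
# interpolate class specs toward their common mean (the separation dial).
spec_to_vector <- function(spec) {
  st <- spec$stripe
  bl <- spec$blotches
  c(base = spec$base_color, brightness = spec$brightness,
    stripe_count = if (is.null(st)) 0 else st$count,
    stripe_width = if (is.null(st)) 0.1 else st$width_frac,
    stripe_color = if (is.null(st)) spec$base_color else st$color,
    blotch_count = if (is.null(bl)) 0 else bl$count,
    blotch_r = if (is.null(bl)) c(0.15, 0.3) else bl$radius_range,
    blotch_color = if (is.null(bl)) spec$base_color else bl$color)
}

vector_to_spec <- function(v, template) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  st_count <- max(0L, as.integer(round(v[["stripe_count"]])))
  bl_count <- max(0L, as.integer(round(v[["blotch_count"]])))
  st_orient <- if (!is.null(template$stripe)) template$stripe$orientation else "vertical"
  rlo <- min(max(v[["blotch_r1"]], 0.02), 0.95)
  rhi <- min(max(v[["blotch_r2"]], rlo), 0.95)
  pattern_spec(
    class_name = template$class_name,
    base_color = clip01(c(v[["base1"]], v[["base2"]], v[["base3"]])),
    stripe = if (st_count >= 1L) list(
      count = st_count, orientation = st_orient,
      width_frac = min(max(v[["stripe_width"]], 0.02), 0.9),
      color = clip01(c(v[["stripe_color1"]], v[["stripe_color2"]],
                       v[["stripe_color3"]]))) else NULL,
    blotches = if (bl_count >= 1L) list(
      count = bl_count, radius_range = c(rlo, rhi),
      color = clip01(c(v[["blotch_color1"]], v[["blotch_color2"]],
                       v[["blotch_color3"]]))) else NULL,
    body_aspect = template$body_aspect,
    noise = template$noise,
    brightness = max(v[["brightness"]], 0.05))
}

#' Blend class specs toward their mean (the class-separation dial)
#'
#' Replaces each class spec's numeric parameters `v` by
#' `mean + separation * (v - mean)`, where the mean is taken across
#' classes. `separation = 1` leaves the specs unchanged; `separation = 0`
#' collapses all classes onto the common mean spec (a null fixture whose
#' labels carry no visual information); values > 1 exaggerate the
#' between-class differences. Noise and body shape are not blended.
#'
#' @param specs List of [pattern_spec()] objects.
#' @param separation Non-negative multiplier.
#' @return List of `pattern_spec` objects.
#' @export
blend_specs <- function(specs, separation = 1) {
  if (!is.numeric(separation) || separation < 0)
    stop_validation("separation must be >= 0")
  V <- t(vapply(specs, spec_to_vector, numeric(15L)))
  mu <- colMeans(V)
  out <- lapply(seq_along(specs), function(i)
    vector_to_spec(mu + separation * (V[i, ] - mu), specs[[i]]))
  names(out) <- if (!is.null(names(specs))) names(specs)
                else vapply(specs, function(s) s$class_name, character(1))
  out
}

#' Generate a labeled multi-class image dataset
#'
#' Renders `n_per_class` images per class after applying the
#' `separation` blend ([blend_specs()]). Per-image seeds are derived
#' deterministically from `seed`.
#'
#' @param specs List of [pattern_spec()] objects (one per class).
#' @param n_per_class Images per class (>= 2).
#' @param size,illumination,strip_frac Passed to
#'   [generate_pattern_image()].
#' @param separation Class-separation multiplier (default 1).
#' @param seed Integer seed.
#' @return A list: `images` (list of [generate_pattern_image()] results,
#'   class-major order), `labels` (data.frame `id`, `class`), `specs`
#'   (the blended specs).
#' @export
generate_class_dataset <- function(specs, n_per_class = 10L,
                                   size = c(128L, 128L), separation = 1,
                                   seed = 1L, illumination = 0.85,
                                   strip_frac = 0.08) {
  if (!is.list(specs) || !length(specs) ||
      !all(vapply(specs, inherits, logical(1), "pattern_spec")))
    stop_validation("specs must be a list of pattern_spec objects")
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 2L) stop_validation("n_per_class must be >= 2")
  blended <- blend_specs(specs, separation)
  images <- list(); labels <- character(0); ids <- character(0)
  k <- 0L
  for (ci in seq_along(blended)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      images[[k]] <- generate_pattern_image(blended[[ci]], size,
                                            seed = derive_seed(seed, k),
                                            illumination = illumination,
                                            strip_frac = strip_frac)
      labels[k] <- specs[[ci]]$class_name
      ids[k] <- sprintf("%s_%02d", specs[[ci]]$class_name, j)
    }
  }
  list(images = images, labels = data.frame(id = ids, class = labels),
       specs = blended)
}

#' Calibrate and crop a synthetic dataset's images
#'
#' Applies [calibrate_white()] against each image's white strip and
#' [crop_body()] to its body box, yielding the `calibrated_image` list
#' that [build_signature_matrix()] consumes.
#'
#' @param ds Result of [generate_class_dataset()].
#' @return List of `calibrated_image` objects in dataset order.
#' @export
prepare_images <- function(ds) {
  lapply(ds$images, function(g)
    crop_body(calibrate_white(g$image, g$ref), g$body))
}

#' End-to-end synthetic pipeline run
#'
#' Convenience driver: generate a class dataset, calibrate and crop,
#' build the signature matrix, and return it as a
#' [signature_dataset()] ready for [loo_success_rate()] or
#' [pairwise_distinguishability()].
#'
#' @inheritParams generate_class_dataset
#' @param mode `"color"` or `"grayscale"`.
#' @param ... Passed on to [build_signature_matrix()] (e.g.
#'   `n_templates`, `size_classes`, `bank`).
#' @return A `signature_dataset`; the template set is attached as
#'   attribute `"templates"`.
#' @export
synthetic_signature_run <- function(specs, n_per_class = 10L,
                                    size = c(128L, 128L), separation = 1,
                                    mode = c("color", "grayscale"),
                                    seed = 1L, ...) {
  mode <- match.arg(mode)
  ds <- generate_class_dataset(specs, n_per_class, size, separation, seed)
  imgs <- prepare_images(ds)
  run <- build_signature_matrix(imgs, mode = mode, seed = derive_seed(seed, 999L),
                                ids = ds$labels$id, ...)
  out <- signature_dataset(run$signatures, ds$labels$class,
                           ids = ds$labels$id, mode = mode)
  attr(out, "templates") <- run$templates
  out
}

#' Default pattern-class palette
#'
#' Six configurable example classes spanning the generator's axes: two
#' plain-vs-striped brown classes (`A`, `B`), a blotched brown (`C`), a
#' bright-striped brown (`E`), a plain green (`L`) and a bright
#' high-contrast green (`F`). The names are labels, not claims about any
#' real animal's patterns.
#'
#' @param noise Noise list applied to every class (see [pattern_spec()]).
#' @return Named list of [pattern_spec()] objects.
#' @export
default_pattern_specs <- function(noise = list(hue_sd = 0.02,
                                               placement_sd = 0.02,
                                               pixel_sd = 0.02)) {
  brown <- c(0.45, 0.33, 0.20)
  list(
    A = pattern_spec("A", brown, noise = noise),
    B = pattern_spec("B", brown,
                     stripe = list(count = 1L, orientation = "horizontal",
                                   width_frac = 0.22,
                                   color = c(0.78, 0.70, 0.52)),
                     noise = noise),
    C = pattern_spec("C", c(0.50, 0.38, 0.25),
                     blotches = list(count = 5L, radius_range = c(0.12, 0.28),
                                     color = c(0.30, 0.22, 0.14)),
                     noise = noise),
    E = pattern_spec("E", c(0.42, 0.32, 0.20),
                     stripe = list(count = 3L, orientation = "vertical",
                                   width_frac = 0.10,
                                   color = c(0.85, 0.75, 0.25)),
                     noise = noise),
    L = pattern_spec("L", c(0.33, 0.55, 0.24), noise = noise),
    F = pattern_spec("F", c(0.28, 0.60, 0.22), brightness = 1.25,
                     stripe = list(count = 2L, orientation = "vertical",
                                   width_frac = 0.12,
                                   color = c(0.90, 0.88, 0.45)),
                     noise = noise))
}

#' Color with matched luminance
#'
#' Returns the RGB color with the requested red and blue components whose
#' BT.601 luminance equals that of `reference`; the green component is
#' solved from `0.299 R + 0.587 G + 0.114 B = L(reference)`. Used to
#' build constant-luminance hue-rotated image pairs, which differ for the
#' color pathway but are identical to the grayscale (pattern-only)
#' pathway.
#'
#' @param reference RGB color whose luminance to match.
#' @param red,blue Desired red and blue components.
#' @return Length-3 RGB color in \[0, 1\].
#' @export
matched_luminance_color <- function(reference, red, blue) {
  L <- sum(c(0.299, 0.587, 0.114) * reference)
  g <- (L - 0.299 * red - 0.114 * blue) / 0.587
  if (g < 0 || g > 1)
    stop_validation("no in-gamut green component matches this luminance; ",
                    "choose different red/blue values")
  c(red, g, blue)
}

#' Generate a synthetic capture-metadata table
#'
#' Emulates capture records in which the probability of brown (vs green)
#' body color follows a logistic model in capture month and snout-vent
#' length: months are uniform over `month_range`, SVL is truncated-normal
#' per sex, and `P(brown) = plogis(intercept + b_month * month + b_svl *
#' svl)`. The defaults encode a seasonal increase in brown coloration
#' (positive month coefficient) that is weaker in larger animals
#' (negative SVL coefficient), with the intercept placed so roughly half
#' the records are brown.
#'
#' @param n Number of records (>= 10).
#' @param month_range Integer month interval (default `c(5, 10)`).
#' @param svl List `mean`, `sd`, `min`, `max` of the truncated-normal
#'   SVL distribution in cm (default mean 10, sd 2, bounds 5-16; used
#'   for both sexes unless a named list `list(male = ..., female = ...)`
#'   is given).
#' @param coef Named vector `intercept`, `month`, `svl` of the
#'   generating logistic model (default `c(-0.23, 0.416, -0.289)`).
#' @param sex_ratio Proportion of males (default 0.5).
#' @param seed Integer seed.
#' @return A data.frame: `id`, `sex` (`"m"`/`"f"`), `month`, `svl`,
#'   `color` (`"brown"`/`"green"`).
#' @export
generate_metadata <- function(n = 148L, month_range = c(5L, 10L),
                              svl = list(mean = 10, sd = 2, min = 5, max = 16),
                              coef = c(intercept = -0.23, month = 0.416,
                                       svl = -0.289),
                              sex_ratio = 0.5, seed = 1L) {
  n <- as.integer(n)
  if (n < 10L) stop_validation("n must be >= 10")
  if (length(month_range) != 2L || month_range[1] > month_range[2])
    stop_validation("month_range must be an ordered integer interval")
  if (!all(c("intercept", "month", "svl") %in% names(coef)))
    stop_validation("coef needs named intercept, month, svl")
  per_sex <- if (all(c("male", "female") %in% names(svl)))
    svl else list(male = svl, female = svl)
  for (s in per_sex)
    if (s$sd <= 0 || s$min >= s$max)
      stop_validation("degenerate SVL distribution: need sd > 0 and min < max")
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < sex_ratio, "m", "f")
    month <- sample(seq(month_range[1], month_range[2]), n, replace = TRUE)
    svl_val <- numeric(n)
    for (s in c("m", "f")) {
      idx <- which(sex == s)
      p <- per_sex[[if (s == "m") "male" else "female"]]
      lo <- stats::pnorm(p$min, p$mean, p$sd)
      hi <- stats::pnorm(p$max, p$mean, p$sd)
      svl_val[idx] <- stats::qnorm(stats::runif(length(idx), lo, hi), p$mean, p$sd)
    }
    eta <- coef[["intercept"]] + coef[["month"]] * month + coef[["svl"]] * svl_val
    brown <- stats::runif(n) < stats::plogis(eta)
    data.frame(id = sprintf("ind%04d", seq_len(n)), sex = sex, month = month,
               svl = svl_val, color = ifelse(brown, "brown", "green"))
  })
}
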