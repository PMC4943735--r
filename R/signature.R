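# Visual signatures: a dictionary of C1-space templates sampled at random
# image locations, and per-image C2 features — the maximal Gaussian
# similarity between each template and the best-matching image location,
# pooled across all positions and scale bands. The signature vector (one
# coordinate per template) is the unit of classification.

#' Sample a template dictionary from a C1 corpus
#'
#' Draws `n_templates` patches of C1 activity at random (image, band,
#' location) triples across the corpus, divided equally among the
#' configured size classes (spatial extents in C1 cells). A size class is
#' sampled uniformly over all band maps large enough to host it; if no
#' band map in the corpus can host a size class, sampling fails. Sampling
#' is deterministic given the seed and corpus order.
#'
#' @param corpus List of [compute_c1()] stacks, all of the same mode and
#'   channel set.
#' @param n_templates Total dictionary size; must be divisible by the
#'   number of size classes (default 200).
#' @param size_classes Template side lengths in C1 cells (default
#'   `c(4, 8, 12, 16)`).
#' @param seed Integer seed controlling the draw.
#' @return An object of class `template_set`: per size class a matrix of
#'   flattened patches (templates x values), the source table
#'   (image, band, row, col, size), `mode`, `seed` and the channel list.
#'   Template order is fixed: signature coordinate i always refers to
#'   template i.
#' @export
sample_templates <- function(corpus, n_templates = 200L,
                             size_classes = c(4L, 8L, 12L, 16L), seed = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L ||
      !all(vapply(corpus, inherits, logical(1), "c1_stack")))
    stop_validation("corpus must be a non-empty list of c1_stack objects")
  modes <- unique(vapply(corpus, function(s) s$mode, character(1)))
  chans <- unique(vapply(corpus, function(s) paste(s$channels, collapse = "|"), character(1)))
  if (length(modes) != 1L || length(chans) != 1L)
    stop_validation("all corpus stacks must share mode and channels")
  size_classes <- sort(as.integer(size_classes))
  n_templates <- as.integer(n_templates)
  k <- length(size_classes)
  if (n_templates < k || n_templates %% k != 0L)
    stop_validation("n_templates must be a positive multiple of the number of size classes")
  per_class <- n_templates %/% k
  # candidate (image, band) pairs per size class
  grids <- lapply(corpus, function(s)
    t(vapply(s$band_defs, function(b) b$grid, integer(2))))
  with_seed(seed, {
    patches <- vector("list", k)
    sources <- vector("list", k)
    for (ci in seq_len(k)) {
      s <- size_classes[ci]
      cand <- do.call(rbind, lapply(seq_along(corpus), function(i) {
        g <- grids[[i]]
        ok <- which(g[, 1] >= s & g[, 2] >= s)
        if (length(ok)) cbind(image = i, band = ok) else NULL
      }))
      if (is.null(cand))
        stop_validation("size class ", s, " does not fit in any C1 band map of the corpus")
      pick <- cand[sample.int(nrow(cand), per_class, replace = TRUE), , drop = FALSE]
      P <- matrix(0, per_class, 0)
      src <- matrix(0L, per_class, 4L)
      vecs <- vector("list", per_class)
      for (j in seq_len(per_class)) {
        i <- pick[j, 1]; b <- pick[j, 2]
        g <- grids[[i]][b, ]
        r <- sample.int(g[1] - s + 1L, 1L)
        cc <- sample.int(g[2] - s + 1L, 1L)
        arr <- band_array(corpus[[i]], b)
        vecs[[j]] <- as.numeric(arr[r:(r + s - 1L), cc:(cc + s - 1L), ])
        src[j, ] <- c(i, b, r, cc)
      }
      patches[[ci]] <- do.call(rbind, vecs)
      sources[[ci]] <- data.frame(image = src[, 1], band = src[, 2],
                                  row = src[, 3], col = src[, 4], size = s)
    }
    structure(
      list(patches = patches, size_classes = size_classes,
           sources = do.call(rbind, sources),
           n_templates = n_templates, mode = modes,
           channels = corpus[[1]]$channels,
           n_orientations = corpus[[1]]$n_orientations, seed = seed),
      class = "template_set")
  })
}

#' Visual signature of an image (C2 features)
#'
#' For each template, scans every scale band and every valid location of
#' the image's C1 stack and records the maximal similarity
#' `exp(-d^2 / (2 * sigma_s^2))` between the template and the local C1
#' patch, where `d` is Euclidean distance and `sigma_s^2` equals the
#' template's dimensionality (so similarity is comparable across size
#' classes). Bands too small to host a template contribute no locations.
#'
#' @param stack A [compute_c1()] stack; its mode and channels must match
#'   the template set's.
#' @param templates A [sample_templates()] dictionary.
#' @param image_id Identifier stored on the result.
#' @return An object of class `visual_signature`: `values` (numeric,
#'   length `templates$n_templates`, all in (0, 1\]), `mode`, `image_id`.
#' @export
compute_signature <- function(stack, templates, image_id = NA_character_) {
  if (!inherits(stack, "c1_stack")) stop_validation("stack must be a c1_stack")
  if (!inherits(templates, "template_set"))
    stop_validation("templates must be a template_set")
  if (!identical(stack$mode, templates$mode) ||
      !identical(stack$channels, templates$channels))
    stop_validation("mode/channel mismatch between C1 stack (", stack$mode,
                    ") and template set (", templates$mode, ")")
  k <- length(templates$size_classes)
  best <- vector("list", k)
  for (ci in seq_len(k))
    best[[ci]] <- rep(-Inf, nrow(templates$patches[[ci]]))
  n_bands <- length(stack$band_defs)
  for (b in seq_len(n_bands)) {
    arr <- band_array(stack, b)
    d <- dim(arr)
    for (ci in seq_len(k)) {
      s <- templates$size_classes[ci]
      if (d[1] < s || d[2] < s) next
      P <- im2col(arr, s)                       # locations x L
      Tm <- templates$patches[[ci]]             # templates x L
      d2 <- cross_sqdist(P, Tm)                 # locations x templates
      best[[ci]] <- pmax(best[[ci]], apply(d2, 2L, min) * -1)
    }
  }
  values <- numeric(templates$n_templates)
  per_class <- templates$n_templates %/% k
  for (ci in seq_len(k)) {
    if (any(!is.finite(best[[ci]])))
      stop_validation("size class ", templates$size_classes[ci],
                      " fits no band of this image's C1 stack")
    L <- ncol(templates$patches[[ci]])
    idx <- (ci - 1L) * per_class + seq_len(per_class)
    values[idx] <- exp(best[[ci]] / (2 * L))    # best holds -min d^2
  }
  structure(list(values = values, mode = stack$mode, image_id = image_id),
            class = "visual_signature")
}

# All s x s x slices patches of a band array, flattened row-major over the
# location grid; column order matches sample_templates' patch flattening.
im2col <- function(arr, s) {
  d <- dim(arr)
  nr <- d[1] - s + 1L; nc <- d[2] - s + 1L
  loc <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  out <- vapply(seq_len(nrow(loc)), function(i) {
    r <- loc$r[i]; cc <- loc$c[i]
    as.numeric(arr[r:(r + s - 1L), cc:(cc + s - 1L), ])
  }, numeric(s * s * d[3]))
  t(out)
}

# squared Euclidean distances between rows of A (n x L) and rows of B (m x L)
cross_sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Full image-to-signature pipeline for a corpus
#'
#' Batch driver: for each calibrated image, optionally downscales it
#' ([resize_max_side()]), derives the pathway channels (luminance alone in
#' grayscale mode; luminance plus the eight single-opponent channels in
#' color mode), computes the C1 stack, samples the template dictionary
#' once from the corpus (or a designated subset), and computes every
#' image's signature against that shared dictionary.
#'
#' By default templates are sampled from all images, including any that
#' will later serve as test items — the classical, mildly optimistic
#' dictionary protocol. Pass `template_images` to restrict sampling (e.g.
#' to training images only) for a strict protocol.
#'
#' @param images List of `calibrated_image` objects (>= 2).
#' @param mode `"color"` or `"grayscale"`.
#' @param bank A [gabor_bank()].
#' @param n_templates,size_classes Passed to [sample_templates()].
#' @param center_sigma,surround_sigma Opponent-channel scales (color mode).
#' @param max_side Working-resolution limit passed to [resize_max_side()].
#' @param seed Integer seed for template sampling.
#' @param template_images Optional integer indices of the images the
#'   dictionary may be sampled from (default: all).
#' @param ids Optional character image identifiers (row names).
#' @param log_path Optional path; if given, a JSON run log (mode, seed,
#'   resolved parameters) is written there.
#' @return A list: `signatures` (n x n_templates matrix, rows in input
#'   order), `templates` (the [sample_templates()] object), `mode`,
#'   `seed`.
#' @export
build_signature_matrix <- function(images, mode = c("color", "grayscale"),
                                   bank = gabor_bank(),
                                   n_templates = 200L,
                                   size_classes = c(4L, 8L, 12L, 16L),
                                   center_sigma = 1, surround_sigma = 3,
                                   max_side = 256L, seed = 1L,
                                   template_images = NULL,
                                   ids = NULL, log_path = NULL) {
  mode <- match.arg(mode)
  if (!is.list(images) || length(images) < 2L)
    stop_validation("need at least 2 images")
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(images))
  stacks <- lapply(images, function(img) {
    img <- resize_max_side(img, max_side)
    chans <- if (mode == "grayscale") {
      list(luminance = to_luminance(img))
    } else {
      c(list(luminance = to_luminance(img)),
        compute_opponent_channels(img, center_sigma, surround_sigma)$maps)
    }
    compute_c1(chans, bank)
  })
  corpus <- if (is.null(template_images)) stacks else stacks[template_images]
  templates <- sample_templates(corpus, n_templates, size_classes, seed)
  sig <- t(vapply(seq_along(stacks), function(i)
    compute_signature(stacks[[i]], templates, ids[i])$values,
    numeric(n_templates)))
  rownames(sig) <- ids
  if (!is.null(log_path))
    write_run_log(list(mode = mode, seed = seed, n_images = length(images),
                       n_templates = n_templates, size_classes = size_classes,
                       max_side = max_side, center_sigma = center_sigma,
                       surround_sigma = surround_sigma,
                       template_images = template_images,
                       pool_sizes = bank$pool_sizes,
                       n_scales = bank$n_scales), log_path)
  list(signatures = sig, templates = templates, mode = mode, seed = seed)
}

#' Read/write signature matrices as CSV
#'
#' The on-disk form is one row per image: an `id` column followed by one
#' column per template (`t1`, `t2`, ...).
#'
#' @param sig Numeric matrix with image ids as row names.
#' @param path CSV file path.
#' @return `write_signatures_csv` returns `path` invisibly;
#'   `read_signatures_csv` returns the matrix with ids as row names.
#' @export
write_signatures_csv <- function(sig, path) {
  df <- data.frame(id = rownames(sig), sig, check.names = FALSE)
  colnames(df) <- c("id", paste0("t", seq_len(ncol(sig))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures_csv
#' @export
read_signatures_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
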