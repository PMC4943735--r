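# Gabor filter bank and the C1 (complex-cell-like) representation:
# absolute Gabor responses at 16 scales and 4 orientations, max-pooled
# over adjacent scale pairs and local spatial neighborhoods on a
# subsampled grid. The result is a shift- and scale-tolerant oriented
# edge-energy map, the substrate both for template sampling and for
# template matching.

#' Gabor filter bank configuration
#'
#' Builds the multi-scale, multi-orientation Gabor bank used by the C1
#' stage. The defaults are the published HMAX parameters: 16 scales with
#' filter sizes 7, 9, ..., 37 px, per-scale effective widths (sigma) and
#' wavelengths increasing with scale, aspect ratio 0.3, and 4 orientations
#' at 0, 45, 90 and 135 degrees. Adjacent scale pairs form 8 bands; band b
#' is spatially max-pooled over `pool_sizes[b]` x `pool_sizes[b]`
#' neighborhoods with half-overlap (subsampling step `ceiling(pool/2)`).
#'
#' Each filter is a cosine Gabor, zero-meaned and normalized to unit L2
#' norm, so responses scale linearly with image contrast.
#'
#' @param n_scales Number of scales; even, >= 2 (scales are pooled in
#'   adjacent pairs).
#' @param n_orientations Number of evenly spaced orientations starting at
#'   0 degrees.
#' @param filter_sizes Odd, strictly increasing filter side lengths, one
#'   per scale.
#' @param effective_widths,wavelengths Per-scale Gabor sigma and
#'   wavelength.
#' @param aspect_ratio Gabor aspect ratio (gamma).
#' @param pool_sizes C1 spatial pooling neighborhood per band
#'   (length `n_scales / 2`).
#' @return An object of class `gabor_bank`: the parameters plus the list
#'   of filter matrices (`filters[[scale]][[orientation]]`) and the band
#'   definitions.
#' @export
gabor_bank <- function(n_scales = 16L,
                       n_orientations = 4L,
                       filter_sizes = seq(7L, by = 2L, length.out = n_scales),
                       effective_widths = c(2.8, 3.6, 4.5, 5.4, 6.3, 7.3, 8.2,
                                            9.2, 10.2, 11.3, 12.3, 13.4, 14.6,
                                            15.8, 17.0, 18.2)[seq_len(n_scales)],
                       wavelengths = c(3.5, 4.6, 5.6, 6.8, 7.9, 9.1, 10.3,
                                       11.5, 12.7, 14.1, 15.4, 16.8, 18.2,
                                       19.7, 21.2, 22.8)[seq_len(n_scales)],
                       aspect_ratio = 0.3,
                       pool_sizes = seq(8L, by = 2L, length.out = n_scales / 2L)) {
  n_scales <- as.integer(n_scales)
  if (n_scales < 2L || n_scales %% 2L != 0L)
    stop_validation("n_scales must be even and >= 2")
  filter_sizes <- as.integer(filter_sizes)
  if (length(filter_sizes) != n_scales || any(filter_sizes %% 2L == 0L) ||
      any(diff(filter_sizes) <= 0L))
    stop_validation("filter_sizes must be odd, strictly increasing, one per scale")
  if (length(effective_widths) != n_scales || length(wavelengths) != n_scales)
    stop_validation("effective_widths and wavelengths must have one value per scale")
  n_bands <- n_scales %/% 2L
  pool_sizes <- as.integer(pool_sizes)
  if (length(pool_sizes) != n_bands || any(pool_sizes < 2L))
    stop_validation("pool_sizes must have n_scales/2 entries >= 2")
  thetas <- pi * (seq_len(n_orientations) - 1L) / n_orientations
  filters <- lapply(seq_len(n_scales), function(s)
    lapply(thetas, function(th)
      gabor_filter(filter_sizes[s], effective_widths[s], wavelengths[s],
                   th, aspect_ratio)))
  structure(
    list(n_scales = n_scales, n_orientations = as.integer(n_orientations),
         filter_sizes = filter_sizes, effective_widths = effective_widths,
         wavelengths = wavelengths, aspect_ratio = aspect_ratio,
         thetas = thetas, n_bands = n_bands, pool_sizes = pool_sizes,
         pool_steps = as.integer(ceiling(pool_sizes / 2)),
         filters = filters),
    class = "gabor_bank")
}

gabor_filter <- function(size, sigma, lambda, theta, gamma) {
  r <- (size - 1L) / 2L
  x <- matrix(rep(-r:r, each = size), size, size)   # column offset
  y <- matrix(rep(-r:r, times = size), size, size)  # row offset
  # theta is the bar orientation measured from horizontal: the carrier
  # runs perpendicular to the bar, so a theta = 0 filter responds to
  # horizontal bars.
  xr <- -x * sin(theta) + y * cos(theta)
  yr <- x * cos(theta) + y * sin(theta)
  g <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda)
  # restrict support to the inscribed disk, as in the standard bank
  g[x^2 + y^2 > r^2] <- 0
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

#' C1 representation of a set of channel maps
#'
#' Convolves every input channel map with every Gabor filter (taking the
#' absolute response, S1), then max-pools adjacent scale pairs over scale
#' and over local spatial neighborhoods on a subsampled grid (C1). Each
#' band's grid positions start at the top-left corner and advance by
#' `pool_steps[band]` (half-overlapping neighborhoods).
#'
#' @param channel_maps Named list of H x W numeric matrices (e.g. the
#'   luminance map alone for the grayscale pathway, or luminance plus the
#'   eight opponent channels for the color pathway). All maps must share
#'   dimensions.
#' @param bank A [gabor_bank()].
#' @return An object of class `c1_stack`: `bands[[channel]][[band]]` is an
#'   h x w x n_orientations array of non-negative pooled responses;
#'   `band_defs` records which scales each band pools and the pooling
#'   grid; `mode` is `"grayscale"` for a single channel and `"color"`
#'   otherwise.
#' @export
compute_c1 <- function(channel_maps, bank = gabor_bank()) {
  if (!inherits(bank, "gabor_bank")) stop_validation("bank must be a gabor_bank")
  if (!is.list(channel_maps) || length(channel_maps) == 0L)
    stop_validation("channel_maps must be a non-empty list of matrices")
  dims <- unique(lapply(channel_maps, dim))
  if (length(dims) != 1L || any(!vapply(channel_maps, is.matrix, logical(1))))
    stop_validation("all channel maps must be matrices of identical dimensions")
  if (any(!vapply(channel_maps, function(m) all(is.finite(m)), logical(1))))
    stop_validation("channel maps must be finite")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  fmax <- max(bank$filter_sizes)
  if (h < fmax || w < fmax)
    stop_validation("image (", h, " x ", w, ") is smaller than the largest Gabor ",
                    "filter (", fmax, "); resize or crop with more margin")
  nch <- length(channel_maps)
  stacked <- array(unlist(channel_maps, use.names = FALSE), dim = c(h, w, nch))
  # S1: |Gabor * map| for every (scale, orientation), all channels batched
  s1 <- lapply(seq_len(bank$n_scales), function(s)
    lapply(seq_len(bank$n_orientations), function(o)
      abs(EBImage::filter2(stacked, bank$filters[[s]][[o]], boundary = 0))))
  for (s in seq_len(bank$n_scales))
    for (o in seq_len(bank$n_orientations))
      if (nch == 1L) s1[[s]][[o]] <- array(s1[[s]][[o]], dim = c(h, w, 1L))
  bands <- rep(list(vector("list", bank$n_bands)), nch)
  band_defs <- vector("list", bank$n_bands)
  for (b in seq_len(bank$n_bands)) {
    s1i <- 2L * b - 1L; s2i <- 2L * b
    pool <- bank$pool_sizes[b]; step <- bank$pool_steps[b]
    r0 <- seq(1L, h - pool + 1L, by = step)
    c0 <- seq(1L, w - pool + 1L, by = step)
    band_defs[[b]] <- list(scales = c(s1i, s2i), pool_size = pool, step = step,
                           grid = c(length(r0), length(c0)))
    for (ch in seq_len(nch)) {
      arr <- array(0, dim = c(length(r0), length(c0), bank$n_orientations))
      for (o in seq_len(bank$n_orientations)) {
        m <- pmax(s1[[s1i]][[o]][, , ch], s1[[s2i]][[o]][, , ch])
        arr[, , o] <- pool_max(m, r0, c0, pool)
      }
      bands[[ch]][[b]] <- arr
    }
  }
  names(bands) <- names(channel_maps)
  structure(
    list(bands = bands, band_defs = band_defs,
         channels = names(channel_maps),
         n_orientations = bank$n_orientations,
         mode = if (nch == 1L) "grayscale" else "color"),
    class = "c1_stack")
}

pool_max <- function(m, r0, c0, pool) {
  out <- matrix(0, length(r0), length(c0))
  for (i in seq_along(r0)) {
    rows <- r0[i]:(r0[i] + pool - 1L)
    sub <- m[rows, , drop = FALSE]
    for (j in seq_along(c0))
      out[i, j] <- max(sub[, c0[j]:(c0[j] + pool - 1L)])
  }
  out
}

# Flatten a band of a C1 stack into an h x w x (orientations * channels)
# array; fixed slice order (orientation fastest, then channel) shared by
# template sampling and matching.
band_array <- function(stack, b) {
  slices <- lapply(stack$bands, function(chb) chb[[b]])
  d <- dim(slices[[1]])
  array(unlist(slices, use.names = FALSE),
        dim = c(d[1], d[2], d[3] * length(slices)))
}

#' @export
print.c1_stack <- function(x, ...) {
  g <- vapply(x$band_defs, function(b) paste(b$grid, collapse = "x"), character(1))
  cat("c1_stack (", x$mode, "): ", length(x$channels), " channel(s), ",
      length(x$band_defs), " bands (grids ", paste(g, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
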