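# Single-opponent color channels: center-surround responses in which the
# center is sensitive to one color and the surround to its opponent,
# half-wave rectified into complementary channel pairs so every channel is
# a non-negative "firing rate".

OPPONENT_CHANNEL_NAMES <- c(
  "red_green", "green_red", "yellow_blue", "blue_yellow",
  "red_cyan", "cyan_red", "white_black", "black_white")

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

blur <- function(map, sigma) {
  EBImage::filter2(map, gaussian_kernel(sigma), boundary = "replicate")
}

#' Single-opponent center-surround color channels
#'
#' Computes the eight rectified single-opponent channels of a calibrated
#' RGB image. Each opponent pair (red/green, yellow/blue, red/cyan,
#' white/black) is coded as a signed opponent plane `O = P - Q` (the
#' luminance channel for white/black), and the signed center-surround
#' response is its difference of Gaussians,
#' `S = G(center_sigma) * O  -  G(surround_sigma) * O`:
#' a center tuned to color P against a wider surround tuned to the
#' opponent color Q. Because both Gaussians are unit-normalized, S
#' vanishes on any uniform field. Half-wave rectification splits S into
#' the two complementary channels of the pair: `P_Q = max(S, 0)` and
#' `Q_P = max(-S, 0)`, which jointly carry `|S|` while each stays
#' non-negative. Yellow is `(R + G)/2` and cyan is `(G + B)/2`.
#'
#' @param img A `calibrated_image`.
#' @param center_sigma Gaussian sigma of the center, pixels (default 1).
#' @param surround_sigma Gaussian sigma of the surround, pixels; must
#'   exceed `center_sigma` (default `3 * center_sigma`).
#' @return An object of class `opponent_channels`: `maps` is a named list
#'   of eight non-negative H x W matrices
#'   (`red_green`, `green_red`, `yellow_blue`, `blue_yellow`, `red_cyan`,
#'   `cyan_red`, `white_black`, `black_white`); sigmas are recorded.
#' @export
compute_opponent_channels <- function(img, center_sigma = 1,
                                      surround_sigma = 3 * center_sigma) {
  px <- image_pixels(img)
  if (!is_scalar_number(center_sigma) || !is_scalar_number(surround_sigma) ||
      center_sigma <= 0 || surround_sigma <= center_sigma)
    stop_validation("need surround_sigma > center_sigma > 0")
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  opponent_planes <- list(
    rg = r - g,
    yb = (r + g) / 2 - b,
    rc = r - (g + b) / 2,
    wb = to_luminance(img))
  maps <- vector("list", 8L)
  names(maps) <- OPPONENT_CHANNEL_NAMES
  for (i in seq_along(opponent_planes)) {
    o <- opponent_planes[[i]]
    s <- blur(o, center_sigma) - blur(o, surround_sigma)
    maps[[2L * i - 1L]] <- pmax(s, 0)
    maps[[2L * i]] <- pmax(-s, 0)
  }
  structure(
    list(maps = maps, center_sigma = center_sigma, surround_sigma = surround_sigma),
    class = "opponent_channels")
}
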