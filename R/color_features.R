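#' RGB to HSI color conversion
#'
#' Converts unit-interval RGB values to the hue/saturation/intensity
#' (HSI) color space, which separates chromatic content (H, S) from
#' brightness (I).  Hue is computed with the two-argument arctangent of
#' \eqn{(\sqrt{3}(G-B),\ (R-G)+(R-B))} and wrapped to \eqn{[0, 2\pi)}, so
#' the full hue circle is reachable; this is equivalent to the classical
#' \eqn{\cos^{-1}} formulation.  Saturation is
#' \eqn{1 - 3\min(R,G,B)/(R+G+B)} and intensity \eqn{(R+G+B)/3}.
#'
#' Achromatic pixels (R = G = B, including black) are assigned H = 0 and
#' S = 0 by convention: the hue formula is 0/0 there, and any fixed hue
#' is equivalent because zero saturation removes its influence.
#'
#' @param r,g,b Numeric vectors of equal length with values in [0, 1]
#'   (8-bit channels divided by 255).
#' @return A list with numeric vectors `h` (radians in [0, 2pi)), `s`
#'   and `i` (both in [0, 1]).
#' @examples
#' rgb_to_hsi(1, 0, 0)   # pure red: h = 0, s = 1, i = 1/3
#' rgb_to_hsi(0, 1, 0)   # pure green: h = 2*pi/3
#' @export
rgb_to_hsi <- function(r, g, b) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  if (length(r) == 0L) stop("empty input")
  if (any(r < 0 | r > 1 | g < 0 | g > 1 | b < 0 | b > 1, na.rm = TRUE))
    stop("RGB components must lie in [0, 1]")
  achrom <- (r == g) & (g == b)
  h <- atan2(sqrt(3) * (g - b), (r - g) + (r - b))
  h <- ifelse(h < 0, h + 2 * pi, h)
  h[h >= 2 * pi] <- 0
  total <- r + g + b
  s <- numeric(length(r))
  nz <- !achrom
  s[nz] <- 1 - 3 * pmin(r[nz], g[nz], b[nz]) / total[nz]
  h[achrom] <- 0
  s[s < 0] <- 0
  s[s > 1] <- 1
  list(h = h, s = s, i = total / 3)
}

#' Assemble the six-dimensional pixel feature vector
#'
#' Builds the (r, g, b, h, s, i) descriptor used by all clustering and
#' classification steps.  By default the hue angle is divided by
#' \eqn{2\pi} so that all six components share the [0, 1] range and no
#' single feature dominates Euclidean distances; set `scale_hue = FALSE`
#' to keep hue in radians.
#'
#' @param r,g,b Numeric vectors in [0, 1].
#' @param scale_hue Logical; divide hue by 2*pi (default `TRUE`).
#' @return Numeric matrix with one row per pixel and columns
#'   `r,g,b,h,s,i`.
#' @export
make_feature_vector <- function(r, g, b, scale_hue = TRUE) {
  hsi <- rgb_to_hsi(r, g, b)
  h <- if (scale_hue) hsi$h / (2 * pi) else hsi$h
  m <- cbind(r = r, g = g, b = b, h = h, s = hsi$s, i = hsi$i)
  rownames(m) <- NULL
  m
}

#' Convert an RGB raster to per-pixel feature vectors
#'
#' @param img Numeric array `height x width x 3` with values in [0, 1],
#'   or an integer array of 8-bit values in [0, 255] (divided by 255).
#' @param scale_hue Logical; see [make_feature_vector()].
#' @return Numeric matrix `n_pixels x 6` in row-major pixel order (all
#'   pixels of the first image row, then the second, ...), with
#'   attributes `img_dim = c(height, width)` and `coords` (a two-column
#'   row/col matrix) for reassembly.
#' @export
image_to_features <- function(img, scale_hue = TRUE) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("img must be a height x width x 3 array")
  if (prod(dim(img)[1:2]) == 0L) stop("empty image")
  if (max(img, na.rm = TRUE) > 1) img <- img / 255
  h <- dim(img)[1]; w <- dim(img)[2]
  # row-major pixel order: transpose each channel before flattening
  r <- as.vector(t(img[, , 1]))
  g <- as.vector(t(img[, , 2]))
  b <- as.vector(t(img[, , 3]))
  m <- make_feature_vector(r, g, b, scale_hue = scale_hue)
  attr(m, "img_dim") <- c(h, w)
  attr(m, "coords") <- cbind(
    row = rep(seq_len(h), each = w),
    col = rep(seq_len(w), times = h)
  )
  m
}

# Reassemble a per-pixel vector (in the order produced by
# image_to_features) into a height x width matrix.
vector_to_raster <- function(v, img_dim) {
  matrix(v, nrow = img_dim[1], ncol = img_dim[2], byrow = TRUE)
}
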