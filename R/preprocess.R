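# Raw-image normalization ahead of detection.

#' Rotate landscape images to portrait orientation
#'
#' If the image is wider than tall, applies a lossless 90-degree
#' counter-clockwise rotation; otherwise returns the input unchanged. The
#' operation is idempotent and pixel-count preserving, and downstream stages
#' are rotation-agnostic so the direction is a fixed convention.
#'
#' @param image H x W matrix or H x W x 3 array.
#' @return The portrait-oriented image (height >= width).
#' @export
#' @examples
#' img <- array(runif(600 * 800 * 3), c(600, 800, 3))
#' dim(normalizeOrientation(img))  # 800 600 3
normalizeOrientation <- function(image) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] == 0L)) stop("empty image")
  if (d[2L] <= d[1L]) return(image)
  rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  if (length(d) == 2L) rot90ccw(image)
  else {
    out <- array(0, dim = c(d[2L], d[1L], d[3L]))
    for (k in seq_len(d[3L])) out[, , k] <- rot90ccw(image[, , k])
    out
  }
}

#' Down-sample an image to half size
#'
#' Area interpolation: each output pixel is the exact mean of a 2 x 2 input
#' block. Odd trailing rows/columns are dropped (floor division); values are
#' kept on the continuous 0-255 scale without re-quantization, so a 2 x 2
#' checkerboard of 0/255 averages to exactly 127.5.
#'
#' @param image H x W matrix or H x W x 3 array with H, W >= 2.
#' @return Image of shape floor(H/2) x floor(W/2).
#' @export
downsampleHalf <- function(image) {
  d <- dim(image)
  if (is.null(d) || d[1L] < 2L || d[2L] < 2L) stop("image must be at least 2 x 2")
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  pool <- function(m) {
    m <- m[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
    (m[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L)] +
     m[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L)] +
     m[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L)] +
     m[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L)]) / 4
  }
  if (length(d) == 2L) pool(image)
  else {
    out <- array(0, dim = c(h2, w2, d[3L]))
    for (k in seq_len(d[3L])) out[, , k] <- pool(image[, , k])
    out
  }
}
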