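# Shared low-level primitives.
#
# Image convention throughout the package: an RGB image is a numeric array
# with dim c(H, W, 3) and values on the 0-255 scale; a mask is a logical
# H x W matrix. Pixel (row r, col c) is addressed 0-based in annotation
# coordinates as x = c - 1, y = r - 1 with its geometric center at
# (x + 0.5, y + 0.5), origin at the top-left corner, x growing rightwards
# (columns) and y growing downwards (rows).

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the prior
#' RNG state afterwards, so library code never clobbers a caller's stream.
#'
#' @param seed single integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive k child seeds from one parent seed, all < 2^31.
deriveSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Label connected components of a binary mask
#'
#' Two foreground pixels belong to one component when they touch edge-to-edge
#' (connectivity 4) or also corner-to-corner (connectivity 8). Labels are
#' renumbered 1..k in raster-scan order of each component's first pixel
#' (row-major: by row, then column), so labelling is deterministic.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 is background.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(labelComponents(m, 4))  # 2 components
#' max(labelComponents(m, 8))  # 1 component
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  h <- nrow(mask)
  idx <- seq_along(fg)                     # vertex ids for foreground pixels
  pos <- integer(length(mask)); pos[fg] <- idx
  r <- ((fg - 1L) %% h) + 1L
  co <- ((fg - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))       # down, right suffice (undirected)
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    rr <- r + o[1L]; cc <- co + o[2L]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= ncol(mask)
    nb <- (cc[ok] - 1L) * h + rr[ok]
    hit <- mask[nb]
    if (any(hit)) edges <- c(edges, rbind(idx[ok][hit], pos[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by raster-scan (column-major storage; convert to row-major order)
  scan_rank <- order(r, co)
  first_seen <- comp[scan_rank][!duplicated(comp[scan_rank])]
  renum <- integer(max(comp)); renum[first_seen] <- seq_along(first_seen)
  lab[fg] <- renum[comp]
  lab
}

# Per-component pixel counts and centroids, in 0-based pixel-center coords.
# Returns data.frame(label, size, cx, cy) ordered by label.
componentStats <- function(lab) {
  ks <- seq_len(max(lab, 0L))
  if (length(ks) == 0L)
    return(data.frame(label = integer(0), size = integer(0),
                      cx = numeric(0), cy = numeric(0)))
  fg <- which(lab > 0L)
  l <- lab[fg]
  h <- nrow(lab)
  rr <- ((fg - 1L) %% h)          # 0-based row
  cc <- ((fg - 1L) %/% h)         # 0-based col
  size <- tabulate(l, nbins = max(ks))
  cx <- as.numeric(tapply(cc + 0.5, l, mean))
  cy <- as.numeric(tapply(rr + 0.5, l, mean))
  data.frame(label = ks, size = size, cx = cx, cy = cy)
}

# Scanline even-odd polygon fill at pixel centers.
# pts: n x 2 matrix of (x, y) vertices, 0-based annotation coordinates.
# Returns logical H x W matrix: TRUE where the pixel center (c-0.5, r-0.5)
# in 1-based terms, i.e. (col-1+0.5, row-1+0.5), lies inside the polygon.
fillPolygon <- function(pts, shape) {
  h <- shape[1L]; w <- shape[2L]
  out <- matrix(FALSE, h, w)
  n <- nrow(pts)
  if (n < 3L) stop("polygon needs at least 3 points")
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- x[c(2:n, 1L)]; yn <- y[c(2:n, 1L)]
  for (r in seq_len(h)) {
    yc <- r - 0.5
    cross <- (y <= yc & yn > yc) | (yn <= yc & y > yc)
    if (!any(cross)) next
    t <- (yc - y[cross]) / (yn[cross] - y[cross])
    xs <- sort(x[cross] + t * (xn[cross] - x[cross]))
    # fill between successive crossing pairs; a column is in when its center
    # lies in the half-open span [xs[i], xs[i+1]) — with half-integer centers
    # and the even-odd rule this matches per-pixel ray casting
    for (i in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- max(ceiling(xs[i] + 0.5), 1L)
      c1 <- min(ceiling(xs[i + 1L] + 0.5) - 1L, w)
      if (c0 <= c1) out[r, c0:c1] <- TRUE
    }
  }
  out
}

# Rasterize a disk (optionally with a low-order radial Fourier boundary
# perturbation). Center in 0-based pixel-center coordinates; radius in px.
# harmonics: data.frame(k, amp, phase) with amp as fraction of radius.
rasterDisk <- function(shape, cx, cy, radius, harmonics = NULL) {
  h <- shape[1L]; w <- shape[2L]
  xc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  yc <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  dx <- xc - cx; dy <- yc - cy
  d <- sqrt(dx^2 + dy^2)
  if (is.null(harmonics) || nrow(harmonics) == 0L) return(d <= radius)
  th <- atan2(dy, dx)
  rb <- radius
  pert <- 0
  for (i in seq_len(nrow(harmonics)))
    pert <- pert + harmonics$amp[i] * cos(harmonics$k[i] * th + harmonics$phase[i])
  d <= rb * (1 + pert)
}

# Clip to [0, 255].
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Apply a function to each channel of an H x W x 3 array.
perChannel <- function(img, f) {
  out <- img
  for (k in seq_len(dim(img)[3L])) out[, , k] <- f(img[, , k])
  out
}

# Gaussian blur of an image or matrix (EBImage backend), 0-255 scale kept.
blurImage <- function(img, sigma) {
  if (sigma <= 0.05) return(img)
  if (length(dim(img)) == 3L)
    perChannel(img, function(m) EBImage::gblur(m, sigma = sigma))
  else EBImage::gblur(img, sigma = sigma)
}

# Affine rotation about the image center by `degrees` (counter-clockwise in
# the x-right / y-down pixel frame). interp: "bilinear" or "nearest";
# out-of-canvas samples use reflect indexing so no synthetic border appears.
rotateAbout <- function(m, degrees, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (degrees == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- degrees * pi / 180
  # inverse map: for each output pixel, sample input at rotation by -th
  X <- matrix(rep(seq_len(w), each = h), h, w) - cx
  Y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  xs <- cos(th) * X + sin(th) * Y + cx
  ys <- -sin(th) * X + cos(th) * Y + cy
  reflect <- function(v, n) {
    # reflect about pixel centers onto [1, n]
    v <- (v - 1) %% (2 * (n - 1))
    v <- ifelse(v > (n - 1), 2 * (n - 1) - v, v)
    v + 1
  }
  if (interp == "nearest") {
    ri <- round(reflect(ys, h)); ci <- round(reflect(xs, w))
    ri <- pmin(pmax(ri, 1), h); ci <- pmin(pmax(ci, 1), w)
    return(matrix(m[cbind(as.vector(ri), as.vector(ci))], h, w))
  }
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  g <- function(rr, cc) {
    rr <- pmin(pmax(reflect(rr, h), 1), h)
    cc <- pmin(pmax(reflect(cc, w), 1), w)
    matrix(m[cbind(as.vector(round(rr)), as.vector(round(cc)))], h, w)
  }
  v <- g(y0, x0) * (1 - fx) * (1 - fy) + g(y0, x0 + 1) * fx * (1 - fy) +
    g(y0 + 1, x0) * (1 - fx) * fy + g(y0 + 1, x0 + 1) * fx * fy
  v
}

# Stable formatting used by all CSV writers: fixed decimals, no scientific.
fmtNum <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}
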