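# Wound-of-interest detection and fixed-size cropping.
#
# Detection backends are pluggable: any function image -> detections
# data.frame works. The package ships a ground-truth oracle backend (for
# phantoms) and a classical circular-edge-voting backend that finds the
# splint annulus. A detection is a row with normalized midpoint (cx, cy),
# normalized extent (w, h) and a confidence score in [0, 1].

#' Construct a detection record
#'
#' @param cx,cy normalized object midpoint in `[0, 1]` (fractions of image
#'   width and height).
#' @param w,h normalized extent in `(0, 1]`.
#' @param confidence score in `[0, 1]`.
#' @return One-row data.frame with columns cx, cy, w, h, confidence.
#' @export
detection <- function(cx, cy, w, h, confidence) {
  stopifnot(cx >= 0, cx <= 1, cy >= 0, cy <= 1, w > 0, w <= 1, h > 0, h <= 1,
            confidence >= 0, confidence <= 1)
  data.frame(cx = cx, cy = cy, w = w, h = h, confidence = confidence)
}

#' Select the wound of interest among multiple detections
#'
#' Returns the detection with the highest confidence score; ties are broken
#' by list order (first wins) so selection is deterministic. An empty input
#' is a no-detection signal, returned as `NULL` (the caller records a
#' missing day rather than failing).
#'
#' @param detections data.frame of detections (possibly 0 rows), or `NULL`.
#' @return One-row data.frame, or `NULL` when nothing was detected.
#' @export
selectWoundOfInterest <- function(detections) {
  if (is.null(detections) || nrow(detections) == 0L) return(NULL)
  detections[which.max(detections$confidence), , drop = FALSE]
}

#' Crop a fixed-size window about a normalized midpoint
#'
#' The side x side window is centered on `(round(cx * W), round(cy * H))`,
#' then translated minimally to lie inside the image (keeping tissue context
#' near borders); if the image is smaller than the window in a dimension,
#' symmetric zero padding completes it. The returned offsets map any crop
#' pixel back to original coordinates exactly:
#' `original_row = crop_row + row_offset` (0-based; negative offsets mean
#' padding).
#'
#' @param image H x W matrix or H x W x 3 array.
#' @param midpoint c(cx, cy), normalized.
#' @param side output side in pixels (default 352).
#' @return List: `crop` (side x side [x 3]), `row_offset`, `col_offset`.
#' @export
cropAboutMidpoint <- function(image, midpoint, side = 352L) {
  d <- dim(image)
  stopifnot(!is.null(d), d[1L] >= 1L, d[2L] >= 1L, side >= 1L)
  h <- d[1L]; w <- d[2L]
  start0 <- function(center_px, n, side) {
    if (n >= side) min(max(center_px - side %/% 2L, 0L), n - side)  # clamp
    else -((side - n) %/% 2L)                                       # pad
  }
  r0 <- start0(as.integer(round(midpoint[2L] * h)), h, as.integer(side))
  c0 <- start0(as.integer(round(midpoint[1L] * w)), w, as.integer(side))
  take <- function(m) {
    out <- matrix(0, side, side)
    rs <- max(r0, 0L); re <- min(r0 + side, h) - 1L
    cs <- max(c0, 0L); ce <- min(c0 + side, w) - 1L
    if (re >= rs && ce >= cs)
      out[(rs - r0 + 1L):(re - r0 + 1L), (cs - c0 + 1L):(ce - c0 + 1L)] <-
        m[(rs + 1L):(re + 1L), (cs + 1L):(ce + 1L), drop = FALSE]
    out
  }
  crop <- if (length(d) == 2L) take(image)
  else {
    out <- array(0, dim = c(side, side, d[3L]))
    for (k in seq_len(d[3L]))
      out[, , k] <- take(matrix(image[, , k], d[1L], d[2L]))
    out
  }
  list(crop = crop, row_offset = r0, col_offset = c0)
}

#' Ground-truth detection oracle for phantom scenes
#'
#' Emits one detection per connected wound component, with midpoint at the
#' component centroid (normalized). The component closest to the scene's
#' recorded wound-of-interest gets confidence 1; any extras get 0.5.
#'
#' @param scene a [PhantomScene-class].
#' @return Detections data.frame, or `NULL` when the wound mask is empty.
#' @export
oracleDetect <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  m <- scene@wound_mask
  if (!any(m)) return(NULL)
  st <- componentStats(labelComponents(m, 8))
  h <- nrow(m); w <- ncol(m)
  tx <- scene@bbox["cx"] * w; ty <- scene@bbox["cy"] * h
  d <- sqrt((st$cx - tx)^2 + (st$cy - ty)^2)
  conf <- ifelse(seq_len(nrow(st)) == which.min(d), 1, 0.5)
  ext <- vapply(st$label, function(k) {
    lab <- labelComponents(m, 8)
    fgi <- which(lab == k)
    rr <- ((fgi - 1L) %% h); cc <- ((fgi - 1L) %/% h)
    c((diff(range(cc)) + 1) / w, (diff(range(rr)) + 1) / h)
  }, numeric(2))
  do.call(rbind, lapply(seq_len(nrow(st)), function(i)
    detection(st$cx[i] / w, st$cy[i] / h,
              max(ext[1L, i], 1 / w), max(ext[2L, i], 1 / h), conf[i])))
}

#' Classical splint detector via circular edge voting
#'
#' Finds ring-shaped reference objects: strong intensity edges vote along
#' their gradient direction for circle centers over a radius range, the
#' accumulator is smoothed, and peaks above a vote floor become detections
#' with the ring center as the wound midpoint. Confidence is the fraction of
#' the best-fitting circle's circumference supported by edge pixels.
#'
#' @param image RGB array or gray matrix (0-255).
#' @param radius_range circle radii searched, as fractions of the shorter
#'   image side (default c(0.12, 0.48)).
#' @param n_radii radius grid size (default 28).
#' @param edge_quantile gradient-magnitude quantile above which pixels vote
#'   (default 0.90).
#' @param min_votes minimum smoothed accumulator peak to accept (default 12).
#' @param max_detections cap on returned circles (default 4).
#' @return Detections data.frame (0 rows when no circle passes the floor).
#' @export
circleDetect <- function(image, radius_range = c(0.12, 0.48), n_radii = 28L,
                         edge_quantile = 0.90, min_votes = 12L,
                         max_detections = 4L) {
  g <- if (length(dim(image)) == 3L)
    (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3 else image
  h <- nrow(g); w <- ncol(g)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- (g[, 3:w] - g[, 1:(w - 2L)]) / 2
  gy[2:(h - 1L), ] <- (g[3:h, ] - g[1:(h - 2L), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(stats::quantile(mag, edge_quantile), 8)
  edge <- which(mag > thr)
  if (length(edge) == 0L) return(detectionFrame0())
  er <- ((edge - 1L) %% h) + 0.5; ec <- ((edge - 1L) %/% h) + 0.5
  ux <- gx[edge] / mag[edge]; uy <- gy[edge] / mag[edge]
  radii <- seq(radius_range[1L], radius_range[2L],
               length.out = n_radii) * min(h, w)
  acc <- matrix(0, h, w)
  for (r in radii) for (s in c(-1, 1)) {
    px <- round(ec + s * r * ux); py <- round(er + s * r * uy)
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    if (any(ok)) {
      ix <- (px[ok] - 1) * h + py[ok]
      tab <- tabulate(ix, nbins = h * w)
      acc <- acc + tab
    }
  }
  acc <- EBImage::gblur(acc, sigma = 2)
  out <- detectionFrame0()
  sup <- matrix(FALSE, h, w)
  xc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  yc <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  for (i in seq_len(max_detections)) {
    acc[sup] <- 0
    peak <- which.max(acc)
    if (acc[peak] < min_votes) break
    py <- ((peak - 1L) %% h) + 0.5; px <- ((peak - 1L) %/% h) + 0.5
    # best radius: mode of edge-pixel distances to this center
    dd <- sqrt((ec - px)^2 + (er - py)^2)
    keep <- dd >= min(radii) & dd <= max(radii)
    if (!any(keep)) break
    hh <- graphics::hist(dd[keep], breaks = 24, plot = FALSE)
    rbest <- hh$mids[which.max(hh$counts)]
    # circumference coverage -> confidence
    on_ring <- abs(dd - rbest) < max(2, 0.05 * rbest)
    angs <- atan2(er[on_ring] - py, ec[on_ring] - px)
    cover <- length(unique(floor((angs + pi) / (2 * pi) * 36))) / 36
    out <- rbind(out, detection(px / w, py / h,
                                min(2 * rbest / w, 1), min(2 * rbest / h, 1),
                                min(cover, 1)))
    sup <- sup | (sqrt((xc - px)^2 + (yc - py)^2) < 0.8 * rbest)
  }
  if (nrow(out) > 0L) out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

detectionFrame0 <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), w = numeric(0),
             h = numeric(0), confidence = numeric(0))
}
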