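# Independent brute-force oracles, deliberately written with none of the
# package's internal machinery: per-pixel ray casting for polygon fill,
# breadth-first flood fill for component labelling, and exhaustive search
# for component selection.

# even-odd point-in-polygon by ray casting (crossings strictly right of the
# point); pts is n x 2 (x, y)
oraclePointInPolygon <- function(px, py, pts) {
  n <- nrow(pts)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- pts[i, 1]; y1 <- pts[i, 2]; x2 <- pts[j, 1]; y2 <- pts[j, 2]
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (xc > px) inside <- !inside
    }
  }
  inside
}

oraclePolygonMask <- function(pts, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2]))
    out[r, c] <- oraclePointInPolygon(c - 0.5, r - 0.5, pts)
  out
}

# BFS flood-fill labelling
oracleLabel <- function(mask, connectivity) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 4) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
        else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  k <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    k <- k + 1L
    queue <- list(c(r, cc)); lab[r, cc] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        rr <- p[1] + nb[d, 1]; c2 <- p[2] + nb[d, 2]
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- k
          queue[[length(queue) + 1]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# brute-force "most central component above min size"
oracleCentral <- function(mask, min_size, centroid, connectivity = 8) {
  lab <- oracleLabel(mask, connectivity)
  best <- 0L; bestd <- Inf
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) <= min_size) next
    cy <- mean(px[, 1] - 0.5); cx <- mean(px[, 2] - 0.5)
    d <- sqrt((cx - centroid[1])^2 + (cy - centroid[2])^2)
    if (d < bestd) { bestd <- d; best <- k }
  }
  if (best == 0L) mask & FALSE else lab == best
}

# random blobby mask: a few disks on a small canvas
randomBlobMask <- function(shape, n_blobs, rmax = 6) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 1, shape[2] - 1); cy <- runif(1, 1, shape[1] - 1)
    r <- runif(1, 1, rmax)
    for (rr in seq_len(shape[1])) for (cc in seq_len(shape[2]))
      if ((cc - 0.5 - cx)^2 + (rr - 0.5 - cy)^2 <= r^2) m[rr, cc] <- TRUE
  }
  m
}

# small, fast clean phantom used by several files
tinyScene <- function(seed = 11, day = 0, mpp = 0.12, ...) {
  renderPhantom(healing = healingParams(noise_sd = 0),
                corruption = corruptionSpec(...), day = day,
                mm_per_pixel = mpp, seed = seed)
}
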