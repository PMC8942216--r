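# Deterministic classical segmentation backend.
#
# Phantom scenes are rendered from a known palette, so nearest-palette-color
# classification segments them exactly when uncorrupted. This backend makes
# post-processing and measurement testable without any training, and its
# failure modes under corruption (occluded wound pixels drop out, blur eats
# the boundary) exercise the robustness machinery.

#' Color-distance reference segmenter
#'
#' Assigns each pixel to its nearest palette color (skin, wound, splint,
#' occluder); a pixel scores 255 on the wound channel when its nearest color
#' is the wound color and the distance is below `max_color_distance`. The
#' splint-inner channel is reconstructed geometrically: the splint-colored
#' annulus is hole-filled and the annulus itself subtracted, leaving the
#' filled inner disk (wound included), which is the reference region the
#' area calibration needs.
#'
#' @param crop H x W x 3 array (0-255).
#' @param palette named list of RGB vectors as from [phantomPalette()].
#' @param max_color_distance maximum RGB distance to accept a class
#'   assignment (default 60; zero-padded borders match nothing).
#' @return A [ProbabilityMaps-class] with hard 0/255 scores.
#' @export
referenceSegment <- function(crop, palette = phantomPalette(),
                             max_color_distance = 60) {
  d <- dim(crop)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  n <- d[1L] * d[2L]
  px <- cbind(as.vector(crop[, , 1L]), as.vector(crop[, , 2L]),
              as.vector(crop[, , 3L]))
  cls <- c("skin", "wound", "splint", "occluder")
  dist2 <- vapply(cls, function(k) {
    col <- palette[[k]]
    (px[, 1L] - col[1L])^2 + (px[, 2L] - col[2L])^2 + (px[, 3L] - col[3L])^2
  }, numeric(n))
  nearest <- max.col(-dist2, ties.method = "first")
  ok <- dist2[cbind(seq_len(n), nearest)] <= max_color_distance^2
  wound <- matrix(255 * (nearest == 2L & ok), d[1L], d[2L])
  annulus <- matrix(nearest == 3L & ok, d[1L], d[2L])
  splint <- matrix(0, d[1L], d[2L])
  if (any(annulus)) {
    ring <- largestComponent(annulus, 8)
    inner <- (EBImage::fillHull(ring) > 0) & !ring
    splint[inner] <- 255
  }
  probabilityMaps(wound, splint)
}
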