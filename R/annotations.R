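# Polygon annotations (LabelMe dialect), label masks, measurement tables.
#
# Annotation coordinates are 0-based with x = column, y = row and origin at
# the top-left corner; the center of pixel (row r, col c) is (c + 0.5,
# r + 0.5). Polygon fill uses the even-odd rule evaluated at pixel centers.

#' A single polygon annotation
#'
#' @slot label "wound" or "splint" (other labels may exist in documents and
#'   are skipped on rasterization/reading with a warning).
#' @slot points n x 2 numeric matrix of (x, y) vertices, 0-based pixel
#'   coordinates, clamped to the image bounds.
#' @slot image_size c(H, W).
#' @export
setClass("PolygonAnnotation",
  representation(label = "character", points = "matrix",
                 image_size = "numeric"),
  validity = function(object) {
    if (nrow(object@points) < 3L) return("polygon needs at least 3 points")
    if (ncol(object@points) != 2L) return("points must be n x 2 (x, y)")
    TRUE
  })

#' @param label,points,image_size see slots.
#' @rdname PolygonAnnotation-class
#' @return `polygonAnnotation()` returns a `PolygonAnnotation`, with points
#'   clamped into the image bounds.
#' @export
polygonAnnotation <- function(label, points, image_size) {
  points <- as.matrix(points)
  if (!is.numeric(points)) stop("malformed coordinates: points must be numeric")
  points[, 1L] <- pmin(pmax(points[, 1L], 0), image_size[2L])
  points[, 2L] <- pmin(pmax(points[, 2L], 0), image_size[1L])
  new("PolygonAnnotation", label = label, points = points,
      image_size = as.numeric(image_size))
}

#' Rasterize polygon annotations into per-label binary masks
#'
#' A pixel belongs to a polygon when its center lies inside it under the
#' even-odd rule; multiple polygons sharing a label are unioned. Labels other
#' than "wound" and "splint" are skipped with a warning (real annotation sets
#' contain auxiliary shapes).
#'
#' @param annotations list of [PolygonAnnotation-class].
#' @param shape c(H, W) of the output masks.
#' @return Named list of logical H x W matrices, one per known label
#'   (`wound`, `splint`); all-FALSE when a label has no polygons.
#' @export
#' @examples
#' sq <- polygonAnnotation("wound",
#'   rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), c(20, 20))
#' sum(polygonsToMask(list(sq), c(20, 20))$wound)  # 100
polygonsToMask <- function(annotations, shape) {
  known <- c("wound", "splint")
  out <- stats::setNames(
    lapply(known, function(l) matrix(FALSE, shape[1L], shape[2L])), known)
  for (a in annotations) {
    stopifnot(is(a, "PolygonAnnotation"))
    if (nrow(a@points) < 3L) stop("polygon needs at least 3 points")
    if (!a@label %in% known) {
      warning(sprintf("skipping annotation with unknown label '%s'", a@label))
      next
    }
    out[[a@label]] <- out[[a@label]] | fillPolygon(a@points, shape)
  }
  out
}

#' Read a LabelMe-style annotation document
#'
#' Expects JSON with `shapes[].label`, `shapes[].points`, `imageHeight`,
#' `imageWidth`. Shapes with unknown labels are kept (rasterization skips
#' them); missing required fields raise a parse error naming the field.
#'
#' @param path JSON file path.
#' @return List of [PolygonAnnotation-class].
#' @export
readAnnotationDocument <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("imageHeight", "imageWidth", "shapes"))
    if (is.null(doc[[f]])) stop(sprintf("annotation parse error: missing '%s'", f))
  size <- c(doc$imageHeight, doc$imageWidth)
  lapply(doc$shapes, function(s) {
    if (is.null(s$label)) stop("annotation parse error: missing 'label'")
    if (is.null(s$points)) stop("annotation parse error: missing 'points'")
    pts <- tryCatch(
      do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p)))),
      warning = function(w) stop("annotation parse error: malformed coordinates"))
    if (is.null(pts) || ncol(pts) != 2L || anyNA(pts))
      stop("annotation parse error: malformed coordinates")
    polygonAnnotation(s$label, pts, size)
  })
}

#' Write annotations as a LabelMe-style JSON document
#'
#' Round trip through [readAnnotationDocument()] preserves labels and
#' coordinates exactly.
#'
#' @param annotations list of [PolygonAnnotation-class].
#' @param path output path.
#' @param image_size c(H, W); defaults to the first annotation's size.
#' @return Invisibly, `path`.
#' @export
writeAnnotationDocument <- function(annotations, path, image_size = NULL) {
  if (is.null(image_size)) {
    if (length(annotations) == 0L)
      stop("image_size required for an empty annotation list")
    image_size <- annotations[[1L]]@image_size
  }
  doc <- list(
    version = "5.0.1", flags = stats::setNames(list(), character(0)),
    shapes = lapply(annotations, function(a) list(
      label = a@label,
      points = lapply(seq_len(nrow(a@points)),
                      function(i) as.numeric(a@points[i, ])),
      shape_type = "polygon")),
    imageHeight = image_size[1L], imageWidth = image_size[2L])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Trace a binary mask into polygon annotations (one per component)
#'
#' Contours are traced through boundary pixel centers, so re-rasterizing the
#' polygon reproduces the mask up to its one-pixel boundary band (pixel count
#' preserved to within the boundary length; see the methods vignette).
#'
#' @param mask logical matrix.
#' @param label annotation label.
#' @return List of [PolygonAnnotation-class] (empty for an empty mask).
#' @export
maskToAnnotations <- function(mask, label) {
  if (!any(mask)) return(list())
  lab <- labelComponents(mask, 8)
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (ct in oc) {
    if (is.null(ct) || nrow(ct) < 3L) next
    # ocontour works in EBImage's frame where dim 1 is x; our dim 1 is rows,
    # so column 1 is the 0-based row index and column 2 the 0-based column
    pts <- cbind(x = ct[, 2L] + 0.5, y = ct[, 1L] + 0.5)
    out[[length(out) + 1L]] <- polygonAnnotation(label, pts, dim(mask))
  }
  out
}

#' Write a per-day measurement table for a set of wound series
#'
#' One row per (wound_id, day), ordered by wound then day; areas printed to
#' 4 decimals and percentages to 2 so re-exports are byte-identical.
#'
#' @param series list of [WoundSeries-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeMeasurementsTable <- function(series, path) {
  stopifnot(length(series) > 0L)
  rows <- do.call(rbind, lapply(series, function(s) {
    r <- s@records
    data.frame(wound_id = s@wound_id, day = r$day, wound_px = r$wound_px,
               splint_px = r$splint_px, area_mm2 = r$area_mm2,
               closure_pct = s@closure, splint_imputed = r$splint_imputed,
               timepoint_filled = r$timepoint_filled,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$wound_id, rows$day), , drop = FALSE]
  rows$wound_px <- fmtNum(rows$wound_px, 1L)
  rows$splint_px <- fmtNum(rows$splint_px, 1L)
  rows$area_mm2 <- fmtNum(rows$area_mm2, 4L)
  rows$closure_pct <- fmtNum(rows$closure_pct, 2L)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
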