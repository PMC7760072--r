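#' Stall geometry: image frame, named regions and static distractors
#'
#' Describes the camera view of a box stall in pixel coordinates (origin at
#' the top-left corner, x rightward, y downward). Regions are named simple
#' polygons used for time-in-region analysis and for anchoring the synthetic
#' behaviour states; distractors are named static points (automatic waterer,
#' manure pile, shoes near the door) that teleport mislabels latch onto.
#'
#' @param width_px,height_px Image size in pixels. Defaults to 2704 x 1520
#'   (2.7K time-lapse footage).
#' @param regions Named list of polygons; each polygon is a two-column
#'   matrix (or data.frame) of x, y vertices, not closed. Must include at
#'   least `front`, `sidewall` and `feeding`.
#' @param distractors Named list of length-2 numeric vectors `c(x, y)`.
#'
#' @return An object of class `stall_geometry`.
#' @examples
#' geo <- stall_geometry()
#' names(geo$regions)
#' @export
stall_geometry <- function(width_px = 2704, height_px = 1520,
                           regions = default_regions(width_px, height_px),
                           distractors = default_distractors(width_px, height_px)) {
  if (length(width_px) != 1 || width_px <= 0 || width_px != round(width_px)) {
    stop_st("width_px must be a positive integer, got %s", width_px)
  }
  if (length(height_px) != 1 || height_px <= 0 || height_px != round(height_px)) {
    stop_st("height_px must be a positive integer, got %s", height_px)
  }
  regions <- lapply(regions, function(p) {
    p <- as.matrix(as.data.frame(p))
    storage.mode(p) <- "double"
    if (ncol(p) != 2 || nrow(p) < 3) stop_st("each region needs >= 3 (x, y) vertices")
    colnames(p) <- c("x", "y")
    p
  })
  if (is.null(names(regions)) || anyDuplicated(names(regions)) || any(names(regions) == "")) {
    stop_st("regions must have unique non-empty names")
  }
  for (nm in names(regions)) {
    p <- regions[[nm]]
    if (any(p[, 1] < 0 | p[, 1] > width_px | p[, 2] < 0 | p[, 2] > height_px)) {
      stop_st("region '%s' has vertices outside the %d x %d image", nm, width_px, height_px)
    }
    if (polygon_self_intersects(p)) {
      stop_st("region '%s' is self-intersecting; regions must be simple polygons", nm)
    }
  }
  for (nm in names(distractors)) {
    d <- distractors[[nm]]
    if (length(d) != 2 || any(d < 0) || d[1] > width_px || d[2] > height_px) {
      stop_st("distractor '%s' must be a point inside the image", nm)
    }
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         regions = regions, distractors = distractors),
    class = "stall_geometry"
  )
}

#' @rdname stall_geometry
#' @export
default_regions <- function(width_px = 2704, height_px = 1520) {
  sx <- width_px / 2704
  sy <- height_px / 1520
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0) * sx, y = c(y0, y0, y1, y1) * sy)
  }
  list(
    # door side of the box, where a watching horse stands with its head out
    front    = rect(0, 0, 1200, 950),
    # far side wall, the usual resting spot
    sidewall = rect(1500, 0, 2704, 950),
    # feeding trough / floor hay area, low in the image
    feeding  = rect(700, 1000, 2100, 1520)
  )
}

#' @rdname stall_geometry
#' @export
default_distractors <- function(width_px = 2704, height_px = 1520) {
  sx <- width_px / 2704
  sy <- height_px / 1520
  list(
    waterer = c(2600 * sx, 1400 * sy),
    manure  = c(300 * sx, 1450 * sy),
    shoes   = c(1350 * sx, 80 * sy)
  )
}

#' @export
print.stall_geometry <- function(x, ...) {
  cat(sprintf("Stall geometry: %d x %d px image\n", x$width_px, x$height_px))
  cat(sprintf("  regions:     %s\n", paste(names(x$regions), collapse = ", ")))
  cat(sprintf("  distractors: %s\n", paste(names(x$distractors), collapse = ", ")))
  invisible(x)
}

# Does the closed polygon given by vertex matrix p self-intersect?
# Brute-force segment pair test; polygons here have a handful of vertices.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # adjacent edges share an endpoint; skip them (and the closing pair)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  a <- s1[1, ]; b <- s1[2, ]; c <- s2[1, ]; e <- s2[2, ]
  d1 <- d(c, e, a); d2 <- d(c, e, b); d3 <- d(a, b, c); d4 <- d(a, b, e)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(c, e, a)) || (d2 == 0 && on_seg(c, e, b)) ||
    (d3 == 0 && on_seg(a, b, c)) || (d4 == 0 && on_seg(a, b, e))
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Ray-casting containment for simple polygons, counting points on an edge
#' or vertex as inside. The boundary-inclusive convention keeps region
#' occupancy deterministic across platforms when tracked points fall exactly
#' on a region border.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param polygon Two-column matrix of polygon vertices (not closed).
#' @return Logical vector, `TRUE` where the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(as.data.frame(polygon))
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- nrow(polygon)
  jx <- px[c(n, seq_len(n - 1))]
  jy <- py[c(n, seq_len(n - 1))]
  vapply(seq_along(x), function(k) {
    xx <- x[k]; yy <- y[k]
    if (is.na(xx) || is.na(yy)) return(NA)
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- px[i]; y1 <- py[i]; x2 <- jx[i]; y2 <- jy[i]
      # on-edge check (collinear and within bounding box)
      cr <- (x2 - x1) * (yy - y1) - (y2 - y1) * (xx - x1)
      if (cr == 0 &&
          min(x1, x2) <= xx && xx <= max(x1, x2) &&
          min(y1, y2) <= yy && yy <= max(y1, y2)) {
        return(TRUE)
      }
      if ((y1 > yy) != (y2 > yy)) {
        xint <- x1 + (yy - y1) * (x2 - x1) / (y2 - y1)
        if (xx < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
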