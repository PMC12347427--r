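## Low-level planar polygon primitives shared by the geometry, meshing and
## zoning code. Polygons are n x 2 matrices (columns x, y in mm), an open ring
## (last vertex is not repeated), oriented counter-clockwise.

#' Signed area of a polygon ring
#'
#' Positive for counter-clockwise orientation (shoelace formula).
#'
#' @param poly numeric matrix, n x 2, open ring.
#' @return signed area in mm^2.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Centroid of a polygon ring
#' @param poly numeric matrix, n x 2, open ring.
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_segments <- function(poly) {
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  cbind(poly, poly[nxt, , drop = FALSE])
}

#' Test points against a polygon
#'
#' Even-odd rule; points exactly on the boundary are classified arbitrarily
#' but deterministically.
#'
#' @param pts n x 2 matrix of query points (a bare length-2 vector is
#'   accepted for a single point).
#' @param poly polygon ring.
#' @return logical vector.
#' @export
points_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  .cpp_point_in_polygon(pts, poly)
}

## TRUE when every vertex of `inner` is inside `outer` and no edges cross.
polygon_inside <- function(inner, outer, eps = 1e-12) {
  if (!all(points_in_polygon(inner, outer))) return(FALSE)
  !.cpp_segments_intersect(polygon_segments(inner), polygon_segments(outer), eps)
}

## Simplicity: no two non-adjacent edges intersect. O(n^2) scan, used on
## contours of a few hundred vertices only.
polygon_is_simple <- function(poly, eps = 1e-12) {
  n <- nrow(poly)
  segs <- polygon_segments(poly)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)] # skip ring-adjacent pair
    if (!length(js)) next
    if (.cpp_segments_intersect(segs[i, , drop = FALSE],
                                segs[js, , drop = FALSE], eps))
      return(FALSE)
  }
  TRUE
}

## Insert vertices so no edge exceeds max_len. Keeps orientation.
densify_polygon <- function(poly, max_len) {
  n <- nrow(poly)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(len / max_len))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  do.call(rbind, out)
}

rotate_points <- function(pts, angle_deg, center = c(0, 0)) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

translate_points <- function(pts, v) sweep(pts, 2, v, `+`)

rotate_vec <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

## Ensure CCW orientation.
orient_ccw <- function(poly) {
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Export a polygon as a WKT POLYGON string
#' @param poly polygon ring (n x 2 matrix).
#' @return character scalar in Well-Known Text.
#' @export
polygon_wkt <- function(poly) {
  ring <- rbind(poly, poly[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", ring[, 1], ring[, 2]), collapse = ", "))
}

validate_contour <- function(poly, what = "contour") {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
    stop(what, ": need a matrix with >= 3 vertices and 2 columns")
  if (!all(is.finite(poly))) stop(what, ": non-finite coordinates")
  if (polygon_area(poly) <= 0) stop(what, ": not counter-clockwise / zero area")
  if (!polygon_is_simple(poly)) stop(what, ": self-intersecting")
  invisible(poly)
}
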