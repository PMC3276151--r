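# Outline standardization and centroid-based size metrics.  An outline is
# an ordered (x, y) vertex matrix; the polygon is implicitly closed from
# the last vertex back to the first, and that artificial closure segment
# is the "baseline" (in the study the baseline joins the two ends of the
# manually traced lobe margin, where the lateral plate meets the lobe).

# shoelace signed area of the implicitly closed polygon (positive =
# counterclockwise)
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# area centroid of the implicitly closed polygon
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# TRUE if any two non-adjacent edges of the closed polygon properly cross
has_self_intersection <- function(xy) {
  n <- nrow(xy)
  p1 <- xy
  p2 <- xy[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip edges adjacent through the closure
    if (!length(j)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p1[i, 1], length(j)), rep(p1[i, 2], length(j)))
    d4 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p2[i, 1], length(j)), rep(p2[i, 2], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Standardize a raw outline
#'
#' Places an outline in the standard configuration used for morphometry:
#' the polygon is closed through the artificial baseline (the segment from
#' the last vertex back to the first), rotated so the baseline is
#' horizontal (the vector from the first to the last baseline endpoint
#' points along +x), mirrored about the x-axis if the signed area violates
#' the clockwise handedness convention, and translated so the area
#' centroid sits at the origin.  The operation is idempotent and invariant
#' to rotation, translation and mirroring of the input.
#'
#' @param xy Two-column matrix of ordered outline vertices (the open
#'   trace; the closure edge is the baseline).
#' @param baseline Indices of the two baseline endpoints (default: first
#'   and last vertex).
#' @param check_simple If `TRUE`, warn and flag the result when the closed
#'   polygon self-intersects.
#' @return The standardized vertex matrix, class `standard_outline`, with
#'   attribute `self_intersecting` when flagged.
#' @examples
#' sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
#' standardize_outline(sq)
#' @export
standardize_outline <- function(xy, baseline = c(1L, nrow(xy)),
                                check_simple = TRUE) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("an outline needs at least 3 points")
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  dup <- rowSums((xy - xy[c(nrow(xy), 1:(nrow(xy) - 1)), ])^2) == 0
  dup[1] <- FALSE
  if (any(dup)) xy <- xy[!dup, , drop = FALSE]
  if (nrow(xy) < 3) stop("an outline needs at least 3 distinct points")
  b <- xy[baseline[2], ] - xy[baseline[1], ]
  th <- atan2(b[2], b[1])
  R <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
  out <- xy %*% t(R)
  if (signed_area(out) > 0) out[, 2] <- -out[, 2]  # enforce clockwise
  ctr <- polygon_centroid(out)
  out <- sweep(out, 2, ctr)
  colnames(out) <- c("x", "y")
  flag <- FALSE
  if (check_simple && has_self_intersection(out)) {
    warning("closed outline is self-intersecting; record flagged")
    flag <- TRUE
  }
  structure(out, baseline = baseline, self_intersecting = flag,
            class = c("standard_outline", "matrix", "array"))
}

#' @export
print.standard_outline <- function(x, ...) {
  cat("Standardized outline:", nrow(x), "vertices, area",
      format(abs(signed_area(x)), digits = 4), "\n")
  if (isTRUE(attr(x, "self_intersecting"))) cat("  [flagged: self-intersecting]\n")
  invisible(x)
}

#' @export
plot.standard_outline <- function(x, ...) {
  graphics::plot(rbind(x, x[1, ]), type = "l", asp = 1,
                 xlab = "x", ylab = "y", ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(x)
}

# total chord length of the intersection of a vertical (x = 0) or
# horizontal (y = 0) line with the closed polygon
.axis_chord <- function(xy, axis = c("x", "y")) {
  axis <- match.arg(axis)
  u <- if (axis == "x") xy[, 1] else xy[, 2]   # coordinate tested against 0
  v <- if (axis == "x") xy[, 2] else xy[, 1]   # coordinate of the crossing
  n <- length(u)
  un <- c(u[-1], u[1]); vn <- c(v[-1], v[1])
  cr <- (u < 0) != (un < 0)
  if (!any(cr)) stop("centroid axis misses the polygon (degenerate outline)")
  t <- -u[cr] / (un[cr] - u[cr])
  hits <- sort(v[cr] + t * (vn[cr] - v[cr]))
  if (length(hits) %% 2 == 1) hits <- hits[-length(hits)]  # grazing contact
  sum(hits[seq(2, length(hits), 2)] - hits[seq(1, length(hits), 2)])
}

#' Size metrics of a standardized outline
#'
#' Area of the closed polygon (shoelace formula, baseline region
#' included), lobe height and width as the total chord length of the
#' vertical and horizontal line through the centroid (summed over multiple
#' crossings for non-convex outlines), and the height:width ratio.
#'
#' @param outline A `standard_outline` (centroid at the origin).
#' @return A one-row data frame with `area`, `height`, `width`, `hw`.
#' @examples
#' sq <- standardize_outline(cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5)))
#' size_metrics(sq)
#' @export
size_metrics <- function(outline) {
  xy <- unclass(outline)
  h <- .axis_chord(xy, "x")
  w <- .axis_chord(xy, "y")
  data.frame(area = abs(signed_area(xy)), height = h, width = w, hw = h / w)
}
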