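# Synthetic lobe templates and outline rendering.  These are a synthetic
# stand-in for the dissection images: a smooth, lobe-like closed curve
# whose height and width are calibrated to the measured parental strains
# (b3852: 55.7 x 51.8 um, H:W 1.08; Sam: 46.0 x 66.2 um, H:W 0.70), traced
# as an open polyline whose artificial baseline closes a small gap at the
# bottom, where the lateral plate would join the lobe.  A latent shape
# score stretches the template in height and compresses it in width (or
# vice versa), so area is approximately preserved and higher scores give
# lower H:W (more Sam-like), mirroring the inverse mPC1 / H:W
# relationship.

#' Create a lobe outline template
#'
#' The template is the radial curve
#' `(x, y) = (w/2 cos(t), h/2 sin(t)) * (1 + bulge * sin^2(2t))`: an
#' ellipse with a diagonal bulge that leaves the axis intercepts -- and
#' hence the measured height, width and H:W -- exact while making the
#' outline fuller, like the real lobe.
#'
#' @param height,width Template height and width (mm).
#' @param bulge Diagonal fullness parameter (>= 0; 0 gives an ellipse).
#' @param gap Half-angle (radians) of the bottom opening closed by the
#'   artificial baseline.
#' @return Object of class `lobe_template` with fields `height`, `width`,
#'   `hw`, `bulge`, `gap` and `area` (nominal closed-polygon area).
#' @export
lobe_template <- function(height, width, bulge = 0.12, gap = 0.2) {
  stopifnot(height > 0, width > 0, bulge >= 0, gap > 0, gap < pi / 2)
  tmpl <- structure(list(height = height, width = width,
                         hw = height / width, bulge = bulge, gap = gap),
                    class = "lobe_template")
  tmpl$area <- abs(signed_area(template_outline(tmpl, 256)))
  tmpl
}

#' Parental templates calibrated to the measured strains
#'
#' @return Named list of two `lobe_template`s, `b3852` (tall, narrow,
#'   H:W 1.08) and `sam` (low, broad, H:W 0.70), dimensions in mm.
#' @export
parent_templates <- function() {
  list(b3852 = lobe_template(0.0557, 0.0518),
       sam = lobe_template(0.0460, 0.0662))
}

#' Sample a template as an open outline trace
#'
#' Points run counterclockwise from just after the bottom gap around the
#' lobe to just before it; the implied closure from the last point back to
#' the first is the artificial baseline.
#'
#' @param template A `lobe_template`.
#' @param n_points Number of vertices (>= 32).
#' @return An `n_points x 2` coordinate matrix.
#' @export
template_outline <- function(template, n_points = 128) {
  stopifnot(inherits(template, "lobe_template"))
  if (n_points < 32) stop("need at least 32 outline points")
  g <- template$gap
  tt <- seq(-pi / 2 + g, 3 * pi / 2 - g, length.out = n_points)
  r <- 1 + template$bulge * sin(2 * tt)^2
  cbind(x = template$width / 2 * cos(tt) * r,
        y = template$height / 2 * sin(tt) * r)
}

#' @export
print.lobe_template <- function(x, ...) {
  cat("Lobe template: height", format(x$height, digits = 4),
      "width", format(x$width, digits = 4),
      "H:W", format(x$hw, digits = 4),
      "area", format(x$area, digits = 4), "\n")
  invisible(x)
}

#' Affine score-to-stretch map hitting parental H:W endpoints
#'
#' Solves for `(intercept, slope)` of the affine map `s = b0 + b1 * score`
#' used by [render_lobe_outline()], such that rendering the template at
#' `score_lo` (the parent-A / b3852-like end of the latent scale) measures
#' at `hw_targets[1]` and at `score_hi` at `hw_targets[2]`.  Because the
#' rendered ratio is `template$hw * (1 + s)^2`, the slope is negative:
#' higher scores give lower H:W.
#'
#' @param template A `lobe_template`.
#' @param score_lo,score_hi Latent scores of the two calibration points.
#' @param hw_targets Target H:W ratios at `score_lo` and `score_hi`
#'   (default the parental 1.08 and 0.70).
#' @return Numeric `c(intercept, slope)`.
#' @export
calibrate_score_map <- function(template, score_lo, score_hi,
                                hw_targets = c(1.08, 0.70)) {
  stopifnot(score_hi > score_lo)
  s_lo <- sqrt(hw_targets[1] / template$hw) - 1
  s_hi <- sqrt(hw_targets[2] / template$hw) - 1
  slope <- (s_hi - s_lo) / (score_hi - score_lo)
  c(intercept = s_lo - slope * score_lo, slope = slope)
}

#' Render a lobe outline from a latent shape score
#'
#' Scales the template by `(1 + s)` in height and `1 / (1 + s)` in width,
#' where `s = score_map[1] + score_map[2] * score`, and adds independent
#' Gaussian jitter to every coordinate.  The reciprocal scaling preserves
#' area to second order in `s`.
#'
#' @param score Latent shape value.
#' @param template A `lobe_template`.
#' @param score_map `c(intercept, slope)` of the affine score-to-stretch
#'   map (see [calibrate_score_map()]); the default `c(0, 0)` renders the
#'   template unchanged at any score.
#' @param jitter_sd Coordinate noise SD (same units as the template).
#' @param n_points Number of vertices (>= 32).
#' @param seed Integer seed for the jitter.
#' @return Raw outline matrix (open trace; closure edge = baseline).
#' @export
render_lobe_outline <- function(score, template, score_map = c(0, 0),
                                jitter_sd = 0, n_points = 128, seed = NULL) {
  s <- score_map[1] + score_map[2] * score
  if (1 + s <= 0) stop("shape scale factor (1 + s) must be positive; s = ",
                       format(s, digits = 4))
  xy <- template_outline(template, n_points)
  xy[, 1] <- xy[, 1] / (1 + s)
  xy[, 2] <- xy[, 2] * (1 + s)
  if (jitter_sd > 0) {
    xy <- with_seed(seed, xy + stats::rnorm(length(xy), 0, jitter_sd))
  }
  xy
}
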