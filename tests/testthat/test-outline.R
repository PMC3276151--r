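rot <- function(xy, deg, about = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(xy, 2, about) %*% t(R), 2, about, `+`)
}

# vertex order chosen so the closure edge (baseline) is horizontal
unit_square <- cbind(c(-.5, -.5, .5, .5), c(-.5, .5, .5, -.5))

test_that("standardization is idempotent and rigid-motion invariant", {
  s1 <- standardize_outline(unit_square)
  expect_lt(max(abs(unclass(standardize_outline(unclass(s1))) - unclass(s1))),
            1e-9)
  moved <- sweep(rot(unit_square, 30, about = c(2, -7)), 2, c(11, 3), `+`)
  s2 <- standardize_outline(moved)
  expect_lt(max(abs(unclass(s2) - unclass(s1))), 1e-9)
  # de-rotation leaves the area centroid at the origin
  expect_lt(max(abs(lobeqtl:::polygon_centroid(unclass(s2)))), 1e-9)
})

test_that("mirrored input standardizes to the same outline", {
  tpl <- parent_templates()$b3852
  raw <- render_lobe_outline(0, tpl, n_points = 96)
  mir <- cbind(-raw[, 1], raw[, 2])
  a <- standardize_outline(raw)
  b <- standardize_outline(mir)
  expect_lt(max(abs(unclass(a) - unclass(b))), 1e-9)
})

test_that("handedness convention gives clockwise (negative) signed area", {
  for (xy in list(unit_square, unit_square[4:1, ])) {
    s <- standardize_outline(xy)
    expect_lt(lobeqtl:::signed_area(unclass(s)), 0)
  }
})

test_that("self-intersecting closures are flagged, degenerate inputs error", {
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_warning(s <- standardize_outline(bowtie), "self-intersect")
  expect_true(attr(s, "self_intersecting"))
  expect_error(standardize_outline(unit_square[1:2, ]), "3 points")
  expect_error(standardize_outline(matrix(c(0, 0, 0, 0, 1e300 * 1e10, 1), 3, 2)),
               "finite")
})

test_that("size metrics match closed forms on rectangles", {
  sq <- size_metrics(standardize_outline(unit_square))
  expect_equal(sq$area, 1)
  expect_equal(sq$height, 1)
  expect_equal(sq$width, 1)
  expect_equal(sq$hw, 1)
  rect <- cbind(c(-.5, -.5, .5, .5), c(-1, 1, 1, -1))
  rm <- size_metrics(standardize_outline(rect))
  expect_equal(rm$hw, 2)
  expect_equal(rm$area, 2)
  # height line must cross the polygon
  off <- cbind(c(1, 2, 2, 1), c(1, 1, 2, 2))
  expect_error(size_metrics(off), "degenerate")
})

test_that("parent templates measure at the published H:W endpoints", {
  tpl <- parent_templates()
  hw <- vapply(tpl, function(tp) {
    size_metrics(standardize_outline(render_lobe_outline(0, tp)))$hw
  }, 0)
  expect_lt(abs(hw[["b3852"]] - 1.08), 0.02)
  expect_lt(abs(hw[["sam"]] - 0.70), 0.02)
})

test_that("rendering at s = 0 returns the template trace exactly", {
  tpl <- parent_templates()$sam
  expect_identical(render_lobe_outline(5, tpl, score_map = c(0, 0),
                                       n_points = 64),
                   template_outline(tpl, 64))
  expect_error(render_lobe_outline(0, tpl, score_map = c(-1.5, 0)),
               "positive")
})

test_that("height/width reciprocal scaling approximately preserves area", {
  tpl <- parent_templates()$b3852
  base <- size_metrics(standardize_outline(render_lobe_outline(0, tpl)))
  for (s in c(-0.2, -0.1, 0.1, 0.2)) {
    a <- size_metrics(standardize_outline(
      render_lobe_outline(1, tpl, score_map = c(0, s))))$area
    expect_lt(abs(a - base$area) / base$area, 0.05)
  }
})

test_that("measures are stable in the outline point count", {
  tpl <- parent_templates()$sam
  ref <- size_metrics(standardize_outline(render_lobe_outline(0, tpl,
                                                              n_points = 512)))
  for (np in c(128, 256)) {
    m <- size_metrics(standardize_outline(render_lobe_outline(0, tpl,
                                                              n_points = np)))
    expect_lt(max(abs(unlist(m) / unlist(ref) - 1)), 0.01)
  }
})

test_that("calibrated score map hits both parental endpoints", {
  tpl <- lobe_template(sqrt(0.0557 * 0.0460), sqrt(0.0518 * 0.0662))
  sm <- calibrate_score_map(tpl, -10, 10)
  hw_at <- function(sc) {
    size_metrics(standardize_outline(
      render_lobe_outline(sc, tpl, score_map = sm)))$hw
  }
  expect_lt(abs(hw_at(-10) - 1.08), 0.02)
  expect_lt(abs(hw_at(10) - 0.70), 0.02)
  expect_lt(sm[["slope"]], 0)  # higher score -> lower H:W
})
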