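# Independent oracle for the elliptic Fourier coefficients: trapezoidal
# quadrature of the Fourier integrals of x(s), y(s) against arc length on
# a densely resampled curve.  This is the contour-length parameterization
# the coefficients are defined on; note that an eccentric ellipse traced
# by its angular parameter is *not* a pure first harmonic in arc length,
# so the oracle (not the angular closed form) supplies the expected
# values.
quadrature_efa <- function(xfun, yfun, n, dens = 2e5) {
  th <- seq(0, 2 * pi, length.out = dens + 1)
  x <- xfun(th); y <- yfun(th)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  T <- s[length(s)]
  trap <- function(f) sum(diff(s) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
  t(vapply(seq_len(n), function(k) {
    w <- 2 * pi * k / T
    c(a = 2 / T * trap(x * cos(w * s)), b = 2 / T * trap(x * sin(w * s)),
      c = 2 / T * trap(y * cos(w * s)), d = 2 / T * trap(y * sin(w * s)))
  }, numeric(4)))
}

ellipse256 <- local({
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  cbind(2 * cos(th), sin(th))
})

test_that("25 harmonics yield a 100-coefficient descriptor", {
  ef <- efa_coefficients(ellipse256, 25)
  expect_equal(dim(ef$coef), c(25, 4))
  d <- efa_descriptors(ef)
  expect_length(d, 100)
  expect_equal(names(d)[1:5], c("a1", "b1", "c1", "d1", "a2"))
  expect_true(all(is.finite(d)))
})

test_that("2:1 ellipse coefficients match the arc-length quadrature oracle", {
  ef <- efa_coefficients(ellipse256, 3)
  # frozen oracle values (quadrature_efa at dens = 2e5):
  oracle <- rbind(c(1.82841, 0, 0, 1.07302),
                  c(0, 0, 0, 0),
                  c(0.12893, 0, 0, 0.08928))
  expect_lt(max(abs(ef$coef - oracle)), 1e-3)
  # and the oracle itself reproduces on demand
  live <- quadrature_efa(function(t) 2 * cos(t), sin, 3, dens = 2e4)
  expect_lt(max(abs(live - oracle)), 1e-3)
  # even harmonics vanish by symmetry
  expect_lt(max(abs(ef$coef[2, ])), 1e-3)
})

test_that("a circle is a pure unit first harmonic both ways", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  ef <- efa_coefficients(cbind(cos(th), sin(th)), 4)
  expect_lt(max(abs(ef$coef[1, ] - c(1, 0, 0, 1))), 1e-3)
  expect_lt(max(abs(ef$coef[2:4, ])), 1e-6)
  ef1 <- lobeqtl:::descriptors_to_efa(c(1, 0, 0, 1), T = 2 * pi)
  rc <- efa_reconstruct(ef1, 64)
  expect_lt(max(abs(sqrt(rowSums(rc^2)) - 1)), 1e-9)
})

test_that("descriptors are exactly invariant to pre-centering offsets", {
  ef0 <- efa_coefficients(ellipse256, 5)
  ef1 <- efa_coefficients(sweep(ellipse256, 2, c(3.2, -7.9), `+`), 5)
  expect_equal(ef0$coef, ef1$coef)
  expect_equal(ef1$A0, ef0$A0 + 3.2)
  expect_equal(ef1$C0, ef0$C0 - 7.9)
})

test_that("reversing traversal flips exactly the sine coefficients", {
  tpl <- parent_templates()$b3852
  xy <- standardize_outline(render_lobe_outline(0, tpl, n_points = 100))
  fwd <- efa_coefficients(unclass(xy), 6)
  # reversal keeping the same start vertex
  rev_xy <- unclass(xy)[c(1, 100:2), ]
  bwd <- efa_coefficients(rev_xy, 6)
  expect_equal(bwd$coef[, c("a", "c")], fwd$coef[, c("a", "c")],
               tolerance = 1e-10)
  expect_equal(bwd$coef[, c("b", "d")], -fwd$coef[, c("b", "d")],
               tolerance = 1e-10)
})

test_that("round-trip reconstruction is accurate and improves with n", {
  tpl <- parent_templates()$b3852
  std <- standardize_outline(render_lobe_outline(0, tpl, n_points = 200))
  ef <- efa_coefficients(std, 25)
  h <- size_metrics(std)$height
  # point-to-curve accuracy of the full-harmonic round trip
  expect_lt(max_outline_dev(efa_reconstruct(ef, 300), unclass(std)) / h, 0.01)
  # L2 truncation error against the chord-parameterized curve itself is
  # nonincreasing in the harmonic count (Fourier partial-sum property)
  xy <- unclass(std)
  xyc <- rbind(xy, xy[1, ])
  tt <- c(0, cumsum(sqrt(rowSums(diff(xyc)^2))))
  tq <- seq(0, ef$T, length.out = 513)[-513]
  truth <- cbind(stats::approx(tt, xyc[, 1], xout = tq)$y,
                 stats::approx(tt, xyc[, 2], xout = tq)$y)
  errs <- vapply(1:25, function(k) {
    rec <- efa_reconstruct(ef, 512, n_harm = k)
    sqrt(mean((rec - truth)^2))
  }, 0)
  expect_lt(errs[25] / h, 0.01)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("degenerate outlines are rejected", {
  expect_error(efa_coefficients(matrix(0, 5, 2), 3), "3 distinct|perimeter")
  expect_error(efa_coefficients(ellipse256, 0), "harmonic")
  ef <- efa_coefficients(ellipse256, 2)
  expect_error(efa_reconstruct(ef, 4), "8")
})
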