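# Elliptic Fourier analysis of closed outlines (Kuhl-Giardina).  The x-
# and y-projections of the outline are treated independently as periodic
# functions of contour (chord) length; each harmonic contributes four
# coefficients (a, b for x; c, d for y), so n harmonics give a 4n
# descriptor.  The constant terms A0/C0 are computed but excluded from the
# descriptor because outlines are centroid-centered beforehand, and no
# size or rotation normalization is applied: outlines are already in a
# standard configuration, so normalization would discard real shape
# signal.

#' Elliptic Fourier coefficients of a closed outline
#'
#' Computes the Kuhl-Giardina coefficients for harmonics `1..n` under the
#' chord-length parameterization: the polygon (implicitly closed from the
#' last vertex to the first) is taken as exactly piecewise linear in
#' contour length, for which the Fourier integrals have a closed form.
#'
#' @param outline Two-column vertex matrix (a `standard_outline` or any
#'   closed loop; a duplicated final vertex is tolerated).
#' @param n Number of harmonics (the study uses 25, giving a descriptor of
#'   length 100).
#' @return An object of class `efa`: harmonic count `n`, `coef` (an
#'   `n x 4` matrix with columns `a`, `b`, `c`, `d`), DC terms `A0`, `C0`,
#'   and perimeter `T`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 129)[-129]
#' circ <- cbind(cos(th), sin(th))
#' ef <- efa_coefficients(circ, n = 3)
#' round(ef$coef, 4)
#' @export
efa_coefficients <- function(outline, n) {
  if (n < 1) stop("need at least one harmonic")
  xy <- unclass(as.matrix(outline))
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) stop("an outline needs at least 3 distinct points")
  xyc <- rbind(xy, xy[1, ])
  dx <- diff(xyc[, 1])
  dy <- diff(xyc[, 2])
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) {
    keep <- dt > 0
    dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  }
  tt <- c(0, cumsum(dt))
  T <- tt[length(tt)]
  if (T <= 0) stop("outline has zero perimeter")
  co <- matrix(0, n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  t0 <- tt[-length(tt)]
  t1 <- tt[-1]
  vx <- dx / dt
  vy <- dy / dt
  for (k in seq_len(n)) {
    w <- 2 * pi * k / T
    dcs <- cos(w * t1) - cos(w * t0)
    dsn <- sin(w * t1) - sin(w * t0)
    fac <- T / (2 * pi^2 * k^2)
    co[k, "a"] <- fac * sum(vx * dcs)
    co[k, "b"] <- fac * sum(vx * dsn)
    co[k, "c"] <- fac * sum(vy * dcs)
    co[k, "d"] <- fac * sum(vy * dsn)
  }
  # DC terms: mean of the piecewise-linear x(t), y(t) over one period
  x0 <- xyc[-nrow(xyc), 1]; x1 <- xyc[-1, 1]
  y0 <- xyc[-nrow(xyc), 2]; y1 <- xyc[-1, 2]
  A0 <- sum(dt * (x0 + x1) / 2) / T
  C0 <- sum(dt * (y0 + y1) / 2) / T
  structure(list(n = as.integer(n), coef = co, A0 = A0, C0 = C0, T = T),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat("Elliptic Fourier coefficients:", x$n, "harmonics (",
      4 * x$n, "descriptors ), perimeter", format(x$T, digits = 5), "\n")
  print(round(utils::head(x$coef, 3), 5))
  if (x$n > 3) cat("  ...\n")
  invisible(x)
}

#' Flatten EFA coefficients to the 4n descriptor vector
#'
#' Order: `a1, b1, c1, d1, a2, ...`.  DC terms are excluded.
#'
#' @param ef An `efa` object.
#' @return Named numeric vector of length `4n`.
#' @export
efa_descriptors <- function(ef) {
  stopifnot(inherits(ef, "efa"))
  v <- as.vector(t(ef$coef))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), ef$n),
                     rep(seq_len(ef$n), each = 4))
  v
}

# rebuild an efa object from a descriptor vector (for PCA visualisation)
descriptors_to_efa <- function(v, T = 1) {
  n <- length(v) / 4
  co <- matrix(v, n, 4, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  structure(list(n = as.integer(n), coef = co, A0 = 0, C0 = 0, T = T),
            class = "efa")
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Samples the truncated Fourier series at `m` equal parameter steps.
#'
#' @param ef An `efa` object.
#' @param m Number of points (>= 8).
#' @param n_harm Number of harmonics to use (default: all in `ef`).
#' @param include_dc Include the DC terms (restores the original
#'   location); `FALSE` reconstructs about the origin.
#' @return An `m x 2` matrix of outline vertices (closed loop, first
#'   vertex not repeated).
#' @export
efa_reconstruct <- function(ef, m = 256, n_harm = ef$n, include_dc = TRUE) {
  stopifnot(inherits(ef, "efa"), n_harm >= 1, n_harm <= ef$n)
  if (m < 8) stop("need at least 8 reconstruction points")
  tt <- seq(0, ef$T, length.out = m + 1)[-(m + 1)]
  x <- rep(if (include_dc) ef$A0 else 0, m)
  y <- rep(if (include_dc) ef$C0 else 0, m)
  for (k in seq_len(n_harm)) {
    w <- 2 * pi * k / ef$T
    cs <- cos(w * tt); sn <- sin(w * tt)
    x <- x + ef$coef[k, "a"] * cs + ef$coef[k, "b"] * sn
    y <- y + ef$coef[k, "c"] * cs + ef$coef[k, "d"] * sn
  }
  cbind(x = x, y = y)
}
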