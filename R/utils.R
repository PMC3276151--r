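# Internal numerical and RNG helpers shared across modules.

#' Haldane map function and its inverse
#'
#' Convert between genetic distance in centimorgans and recombination
#' fraction under the Haldane (no-interference) model.
#'
#' @param d Genetic distance in cM.
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return `haldane_r()` returns a recombination fraction; `haldane_d()`
#'   returns a distance in cM.
#' @examples
#' haldane_r(10)
#' haldane_d(haldane_r(10))
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' @rdname haldane_r
#' @export
haldane_d <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

# log10 of the mean of 10^x, computed stably (x on the log10-likelihood scale)
log10meanexp <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1 / length(x), length(x)) else w <- w / sum(w)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(w * 10^(x - m)))
}

# log of sum(exp(x)), stable
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards.  seed = NULL uses (and
# advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# residual sum of squares of Y (matrix or vector) against design X,
# tolerant of rank deficiency
rss_fit <- function(X, Y) {
  Y <- as.matrix(Y)
  qx <- qr(X)
  res <- qr.resid(qx, Y)
  colSums(res^2)
}
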