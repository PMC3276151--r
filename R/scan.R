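# Genome scans over an imputation set.  At each grid position, each
# imputation contributes a likelihood ratio from the single-locus
# regression (additive + dominance codings on autosomes, additive only on
# the hemizygous male X); imputations are combined on the likelihood
# scale, LOD = log10(mean likelihood ratio), computed stably in logs.
# All phenotyped individuals enter the scan: ungenotyped individuals'
# imputations are prior draws, which is what makes selective-genotyping
# analysis unbiased when the non-tail genotypes are recorded as missing.

# centered QTL design columns at grid position p, imputation m
.qtl_cols <- function(imps, p, m) {
  g <- imps$geno[, p, m]
  if (imps$grid$is_x[p]) {
    cbind(a = 2 * g - 3)
  } else {
    cbind(a = g - 2, d = as.numeric(g == 2))
  }
}

# residual sum of squares of centered Y against centered design columns,
# via the pseudo-inverse of the (tiny) normal-equation matrix; gracefully
# handles collinear or constant columns
.rss_reduce <- function(Xc, Yc, rss0) {
  if (is.null(Xc) || ncol(Xc) == 0) return(rss0)
  G <- crossprod(Xc)
  R <- crossprod(Xc, Yc)
  sv <- svd(G)
  pos <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10
  if (!any(pos)) return(rss0)
  Gi <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  pmax(rss0 - colSums(R * (Gi %*% R)), 0)
}

# combine per-imputation log10 likelihood ratios (M x q matrix) into a
# q-vector of LODs
.combine_lod <- function(loglr) {
  mx <- apply(loglr, 2, max)
  lod <- mx + log10(colMeans(10^(sweep(loglr, 2, mx))))
  pmax(lod, 0)
}

# core scan: LOD matrix (positions x phenotypes).  base_cols(m) returns
# centered covariate columns shared across positions (or NULL); extra
# per-position exclusion is handled by cim's own engine.
.scan_core <- function(imps, Y, positions, base_cols = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n != imps$n) stop("phenotype length does not match the imputation set")
  if (anyNA(Y)) stop("phenotype must be present for all individuals")
  Yc <- sweep(Y, 2, colMeans(Y))
  css <- colSums(Yc^2)
  if (any(css == 0)) stop("zero phenotypic variance")
  q <- ncol(Y)
  lod <- matrix(0, length(positions), q)
  for (i in seq_along(positions)) {
    p <- positions[i]
    loglr <- matrix(0, imps$M, q)
    for (m in seq_len(imps$M)) {
      B <- if (is.null(base_cols)) NULL else base_cols(m)
      rss0 <- if (is.null(B)) css else .rss_reduce(B, Yc, css)
      X <- .qtl_cols(imps, p, m)
      Xc <- sweep(X, 2, colMeans(X))
      full <- if (is.null(B)) Xc else cbind(B, Xc)
      rss1 <- .rss_reduce(full, Yc, css)
      loglr[m, ] <- (n / 2) * (log10(pmax(rss0, 1e-300)) -
                               log10(pmax(rss1, 1e-300)))
    }
    lod[i, ] <- .combine_lod(loglr)
  }
  lod
}

new_lod_profile <- function(grid, lod, method, ...) {
  out <- data.frame(chr = grid$chr, pos = grid$pos, lod = lod,
                    stringsAsFactors = FALSE)
  structure(out, method = method, class = c("lod_profile", "data.frame"), ...)
}

#' Interval mapping by multiple imputation
#'
#' Single-QTL genome scan: at every grid position the phenotype is
#' regressed on the imputed genotype codings, the per-imputation
#' likelihood ratios are averaged, and LOD = log10 of that mean.
#'
#' @param imps An [impute_genotypes()] result.
#' @param phenotype Numeric vector, one value per individual (no
#'   missing; ungenotyped individuals are included, their genotypes
#'   having been imputed from the prior).
#' @return A `lod_profile` data frame (`chr`, `pos`, `lod`).
#' @export
interval_mapping <- function(imps, phenotype) {
  stopifnot(inherits(imps, "imputation_set"))
  lod <- .scan_core(imps, phenotype, seq_len(nrow(imps$grid)))
  new_lod_profile(imps$grid, drop(lod), method = "im")
}

#' Composite interval mapping by multiple imputation
#'
#' Interval mapping with marker covariates absorbing linked QTL: markers
#' are chosen by forward selection on their regression RSS, and at each
#' test position any covariate within `window / 2` cM (same chromosome)
#' is dropped from both the null and the full model, so the LOD is
#' relative to the covariate-only model at that position.
#'
#' @param imps An [impute_genotypes()] result.
#' @param phenotype Numeric phenotype vector.
#' @param window Exclusion window in cM (the study used 10).
#' @param n_covariates Number of marker covariates (the study used 4);
#'   `0` reduces exactly to [interval_mapping()].
#' @return A `lod_profile` with attributes `covariates` (selected
#'   markers) and `cov_active` (per-position active covariate names).
#' @export
composite_interval_mapping <- function(imps, phenotype, window = 10,
                                       n_covariates = 4) {
  stopifnot(inherits(imps, "imputation_set"))
  if (window <= 0) stop("window must be > 0")
  if (n_covariates == 0) {
    out <- interval_mapping(imps, phenotype)
    attr(out, "method") <- "cim"
    attr(out, "covariates") <- character(0)
    return(out)
  }
  # marker grid positions (those carrying a map marker)
  key <- paste(imps$map$chr, round(imps$map$pos, 8))
  gkey <- paste(imps$grid$chr, round(imps$grid$pos, 8))
  mk_idx <- match(key, gkey)
  if (n_covariates >= length(mk_idx)) {
    stop("n_covariates must be smaller than the marker count")
  }
  Y <- as.matrix(phenotype)
  Yc <- sweep(Y, 2, colMeans(Y))
  css <- colSums(Yc^2)
  # forward selection on first-imputation marker codings
  cand <- mk_idx
  chosen <- integer(0)
  B <- NULL
  for (k in seq_len(n_covariates)) {
    rss <- vapply(cand, function(p) {
      X <- .qtl_cols(imps, p, 1L)
      Xc <- sweep(X, 2, colMeans(X))
      .rss_reduce(cbind(B, Xc), Yc, css)[1]
    }, 0)
    best <- cand[which.min(rss)]
    chosen <- c(chosen, best)
    Xb <- .qtl_cols(imps, best, 1L)
    B <- cbind(B, sweep(Xb, 2, colMeans(Xb)))
    cand <- setdiff(cand, best)
  }
  cov_tab <- imps$grid[chosen, c("chr", "pos")]
  cov_tab$marker <- imps$map$marker[match(chosen, mk_idx)]
  # per-imputation centered codings of the chosen covariates
  cov_cols <- function(m, keep) {
    if (!length(keep)) return(NULL)
    do.call(cbind, lapply(chosen[keep], function(p) {
      X <- .qtl_cols(imps, p, m)
      sweep(X, 2, colMeans(X))
    }))
  }
  n <- nrow(Y)
  G <- nrow(imps$grid)
  lod <- numeric(G)
  active <- vector("list", G)
  for (p in seq_len(G)) {
    keep <- which(!(cov_tab$chr == imps$grid$chr[p] &
                    abs(cov_tab$pos - imps$grid$pos[p]) <= window / 2))
    active[[p]] <- cov_tab$marker[keep]
    loglr <- matrix(0, imps$M, 1)
    for (m in seq_len(imps$M)) {
      B <- cov_cols(m, keep)
      rss0 <- .rss_reduce(B, Yc, css)
      X <- .qtl_cols(imps, p, m)
      Xc <- sweep(X, 2, colMeans(X))
      rss1 <- .rss_reduce(cbind(B, Xc), Yc, css)
      loglr[m, ] <- (n / 2) * (log10(pmax(rss0, 1e-300)) -
                               log10(pmax(rss1, 1e-300)))
    }
    lod[p] <- .combine_lod(loglr)
  }
  new_lod_profile(imps$grid, lod, method = "cim",
                  covariates = cov_tab, cov_active = active,
                  window = window)
}

# n x P matrix of permuted phenotypes; when strata are given each
# permutation shuffles only within levels, so every stratum keeps its
# own phenotype multiset
permute_within_strata <- function(y, strata, P) {
  n <- length(y)
  vapply(seq_len(P), function(i) {
    if (is.null(strata)) return(y[sample.int(n)])
    out <- y
    for (lv in unique(strata)) {
      idx <- which(strata == lv)
      out[idx] <- y[idx[sample.int(length(idx))]]
    }
    out
  }, numeric(n))
}

#' Permutation significance threshold for a genome scan
#'
#' Permutes the phenotype (within strata when given, the stratified
#' variant required under selective genotyping), recomputes the scan over
#' the scope's chromosomes for every permutation, and returns the
#' empirical `(1 - alpha)` quantile of the genome-maximum LODs, using the
#' `ceiling((1 - alpha) * P)`-th order statistic.  X- and
#' autosome-specific thresholds are obtained by calling with the two
#' scopes.
#'
#' @param imps An [impute_genotypes()] result.
#' @param phenotype Numeric phenotype vector.
#' @param P Number of permutations (the study used 1000).
#' @param alpha Significance level in (0, 1).
#' @param strata Optional factor/vector partitioning individuals
#'   (e.g. genotyped vs ungenotyped); phenotypes are permuted within
#'   levels only.
#' @param scope `"autosome"`, `"X"` or `"all"`.
#' @param seed Integer seed for the permutations.
#' @return Numeric threshold of class `perm_threshold`, with the maxima
#'   and settings as attributes.
#' @export
permutation_threshold <- function(imps, phenotype, P = 1000, alpha = 0.05,
                                  strata = NULL,
                                  scope = c("autosome", "X", "all"),
                                  seed = NULL) {
  stopifnot(inherits(imps, "imputation_set"), P >= 1, alpha > 0, alpha < 1)
  scope <- match.arg(scope)
  y <- as.numeric(phenotype)
  n <- length(y)
  if (!is.null(strata) && length(strata) != n) {
    stop("strata must have one label per individual")
  }
  positions <- switch(scope,
                      autosome = which(imps$grid$chr != "X"),
                      X = which(imps$grid$chr == "X"),
                      all = seq_len(nrow(imps$grid)))
  if (!length(positions)) stop("no grid positions in scope '", scope, "'")
  Yp <- with_seed(seed, permute_within_strata(y, strata, P))
  lod <- .scan_core(imps, Yp, positions)
  maxima <- apply(lod, 2, max)
  k <- ceiling((1 - alpha) * P)
  if (P * alpha < 1) {
    warning("P * alpha < 1; threshold is the maximum permuted LOD")
    k <- P
  }
  thr <- sort(maxima)[k]
  structure(thr, maxima = maxima, alpha = alpha, P = P, scope = scope,
            stratified = !is.null(strata), class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("%s%% %s-scope permutation threshold (P = %d%s): LOD %.3f\n",
              format(100 * (1 - attr(x, "alpha"))), attr(x, "scope"),
              attr(x, "P"),
              if (attr(x, "stratified")) ", stratified" else "",
              as.numeric(x)))
  invisible(x)
}

#' @export
print.lod_profile <- function(x, ...) {
  cat("LOD profile (", attr(x, "method"), "): ", nrow(x),
      " positions on chromosomes ",
      paste(unique(x$chr), collapse = ", "), "\n", sep = "")
  pk <- x[which.max(x$lod), ]
  cat(sprintf("  maximum LOD %.2f at chr %s, %.1f cM\n",
              pk$lod, pk$chr, pk$pos))
  invisible(x)
}

#' Per-chromosome scan summary
#'
#' @param object A `lod_profile`.
#' @param threshold Optional LOD threshold to annotate significance.
#' @param ... Unused.
#' @return Data frame with the peak position and LOD per chromosome.
#' @export
summary.lod_profile <- function(object, threshold = NULL, ...) {
  out <- do.call(rbind, lapply(split(as.data.frame(object), object$chr),
                               function(d) d[which.max(d$lod), ]))
  out <- out[order(match(out$chr, c("X", "2", "3"))), ]
  if (!is.null(threshold)) out$significant <- out$lod >= as.numeric(threshold)
  rownames(out) <- NULL
  out
}

#' Plot a LOD profile
#'
#' @param x A `lod_profile`.
#' @param threshold Optional threshold drawn as a dashed line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lod_profile <- function(x, threshold = NULL, ...) {
  chrs <- unique(x$chr)
  offs <- c(0, cumsum(vapply(chrs, function(cc) max(x$pos[x$chr == cc]) + 10, 0)))
  xg <- x$pos + offs[match(x$chr, chrs)]
  graphics::plot(xg, x$lod, type = "n", xlab = "position",
                 ylab = "LOD", ...)
  for (cc in chrs) {
    i <- x$chr == cc
    graphics::lines(xg[i], x$lod[i])
  }
  graphics::axis(3, at = offs[-length(offs)] +
                   vapply(chrs, function(cc) max(x$pos[x$chr == cc]) / 2, 0),
                 labels = chrs, tick = FALSE)
  if (!is.null(threshold)) graphics::abline(h = as.numeric(threshold), lty = 2)
  invisible(x)
}
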