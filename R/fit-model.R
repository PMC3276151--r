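# Multiple-QTL model fitting over an imputation set.  Per imputation the
# phenotype is regressed jointly on additive (-1/0/+1) and dominance
# (0/1/0) codings of every model locus plus, for each epistatic pair, the
# four cross-products of those codings; estimates are averaged over
# imputations weighted by the imputation's profile likelihood.  Variance
# attribution is by drop-one comparison, hierarchically: dropping a QTL
# also drops the interactions that contain it, so under linkage the
# per-term percentages need not sum to the total (none of this is
# renormalized).

# snap model positions to grid indices; error on coincident loci
.snap_positions <- function(imps, qtl) {
  idx <- integer(nrow(qtl))
  for (i in seq_len(nrow(qtl))) {
    on_chr <- which(imps$grid$chr == as.character(qtl$chr[i]))
    if (!length(on_chr)) stop("no grid positions on chromosome ", qtl$chr[i])
    j <- on_chr[which.min(abs(imps$grid$pos[on_chr] - qtl$pos[i]))]
    idx[i] <- j
  }
  if (anyDuplicated(idx)) {
    d <- which(duplicated(idx) | duplicated(idx, fromLast = TRUE))
    stop("collinear model terms: loci ",
         paste(sprintf("%s@%.1f", qtl$chr[d], qtl$pos[d]), collapse = ", "),
         " map to the same grid position")
  }
  idx
}

# design columns (uncentered, no intercept) for the model at imputation m;
# returns the matrix plus the column span of each term
.model_design <- function(imps, idx, interactions, m, qnames) {
  cols <- list()
  span <- list()
  ntot <- 0L
  for (i in seq_along(idx)) {
    X <- .qtl_cols(imps, idx[i], m)
    colnames(X) <- paste0(qnames[i], ".", colnames(X))
    span[[qnames[i]]] <- ntot + seq_len(ncol(X))
    ntot <- ntot + ncol(X)
    cols[[length(cols) + 1L]] <- X
  }
  for (it in interactions) {
    i <- it[1]; j <- it[2]
    Xi <- cols[[i]]; Xj <- cols[[j]]
    prods <- do.call(cbind, lapply(seq_len(ncol(Xi)), function(ci) {
      out <- Xi[, ci] * Xj
      colnames(out) <- paste0(colnames(Xi)[ci], ":", colnames(Xj))
      out
    }))
    nm <- paste0(qnames[i], ":", qnames[j])
    span[[nm]] <- ntot + seq_len(ncol(prods))
    ntot <- ntot + ncol(prods)
    cols[[length(cols) + 1L]] <- prods
  }
  list(X = do.call(cbind, cols), span = span)
}

#' Fit a multiple-QTL model with epistasis
#'
#' @param imps An [impute_genotypes()] result.
#' @param phenotype Numeric phenotype vector (no missing values).
#' @param qtl Data frame with columns `chr`, `pos` (cM on the scan grid's
#'   scale) and optionally `name` (default `Q1`, `Q2`, ...).  Positions
#'   are snapped to the nearest grid point on their chromosome.
#' @param interactions List of index pairs into `qtl` rows, e.g.
#'   `list(c(1, 2))` for a Q1 x Q2 term.
#' @return Object of class `qtl_fit`: per-QTL effect estimates (`a`,
#'   `d`), per-term percent variance explained and LOD (drop-one), the
#'   interaction terms, and the model totals.
#' @export
fit_qtl_model <- function(imps, phenotype, qtl, interactions = list()) {
  stopifnot(inherits(imps, "imputation_set"), is.data.frame(qtl))
  y <- as.numeric(phenotype)
  if (anyNA(y)) stop("phenotype must be present for all individuals")
  n <- length(y)
  if (n != imps$n) stop("phenotype length does not match the imputation set")
  qnames <- if ("name" %in% names(qtl)) as.character(qtl$name) else
    paste0("Q", seq_len(nrow(qtl)))
  idx <- .snap_positions(imps, qtl)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero phenotypic variance")
  M <- imps$M
  first <- .model_design(imps, idx, interactions, 1L, qnames)
  terms <- names(first$span)
  est <- matrix(0, M, ncol(first$X), dimnames = list(NULL, colnames(first$X)))
  rss_full <- numeric(M)
  rss_drop <- matrix(0, M, length(terms), dimnames = list(NULL, terms))
  for (m in seq_len(M)) {
    des <- if (m == 1L) first else .model_design(imps, idx, interactions, m, qnames)
    X <- cbind(`(Intercept)` = 1, des$X)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients[-1]
    cf[is.na(cf)] <- 0
    est[m, ] <- cf
    rss_full[m] <- sum(fit$residuals^2)
    for (tm in terms) {
      dropc <- des$span[[tm]]
      if (!grepl(":", tm, fixed = TRUE)) {
        # hierarchical drop: interactions containing this QTL go too
        hit <- grepl(paste0("^", tm, ":|:", tm, "$"), terms)
        dropc <- unique(c(dropc, unlist(des$span[terms[hit]])))
      }
      Xr <- cbind(1, des$X[, -dropc, drop = FALSE])
      rss_drop[m, tm] <- sum(stats::lm.fit(Xr, y)$residuals^2)
    }
  }
  # imputation weights: profile likelihood of the full model
  logw <- -(n / 2) * log(rss_full)
  w <- exp(logw - logsumexp(logw))
  lod10 <- function(red) {  # weighted likelihood-scale combination
    lr <- (n / 2) * (log10(red) - log10(rss_full))
    mx <- max(lr)
    pmax(mx + log10(sum(w * 10^(lr - mx))), 0)
  }
  pct <- function(red) sum(w * 100 * (red - rss_full) / tss)
  term_pct <- vapply(terms, function(tm) pct(rss_drop[, tm]), 0)
  term_lod <- vapply(terms, function(tm) lod10(rss_drop[, tm]), 0)
  coefs <- colSums(est * w)
  qtab <- data.frame(name = qnames, chr = as.character(qtl$chr),
                     pos = imps$grid$pos[idx],
                     a = unname(coefs[paste0(qnames, ".a")]),
                     d = ifelse(paste0(qnames, ".d") %in% names(coefs),
                                unname(coefs[paste0(qnames, ".d")]), NA),
                     pct_var = unname(term_pct[qnames]),
                     lod = unname(term_lod[qnames]),
                     stringsAsFactors = FALSE)
  inames <- setdiff(terms, qnames)
  itab <- if (length(inames)) {
    data.frame(term = inames,
               pct_var = unname(term_pct[inames]),
               lod = unname(term_lod[inames]),
               stringsAsFactors = FALSE)
  } else data.frame(term = character(0), pct_var = numeric(0), lod = numeric(0))
  structure(list(qtl = qtab, interactions = itab,
                 interaction_pairs = interactions,
                 coefficients = coefs,
                 total_pct_var = sum(w * 100 * (1 - rss_full / tss)),
                 total_lod = lod10(rep(tss, M)),
                 n = n, M = M, tss = tss, grid_idx = idx,
                 weights = w),
            class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Multiple-QTL model fit (n = %d, M = %d imputations)\n",
              x$n, x$M))
  cat(sprintf("  total variance explained: %.1f%%  (model LOD %.2f)\n",
              x$total_pct_var, x$total_lod))
  q <- x$qtl
  q$pos <- round(q$pos, 1)
  q[c("a", "d", "pct_var", "lod")] <-
    lapply(q[c("a", "d", "pct_var", "lod")], round, digits)
  print(q, row.names = FALSE)
  if (nrow(x$interactions)) {
    it <- x$interactions
    it[c("pct_var", "lod")] <- lapply(it[c("pct_var", "lod")], round, digits)
    print(it, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.qtl_fit <- function(object, ...) object$coefficients

#' @export
summary.qtl_fit <- function(object, ...) {
  list(qtl = object$qtl, interactions = object$interactions,
       total_pct_var = object$total_pct_var, total_lod = object$total_lod)
}

#' Scan for a QTL to add to a fitted model
#'
#' Profiles the LOD of adding one locus (additive + dominance) to a base
#' model whose terms act as covariates, over the whole grid.
#'
#' @inheritParams fit_qtl_model
#' @return A `lod_profile` (method `"addqtl"`).  Positions coincident
#'   with a modeled locus give LOD ~ 0 because the added columns are
#'   collinear with the base model.
#' @export
scan_additional <- function(imps, phenotype, qtl, interactions = list()) {
  stopifnot(inherits(imps, "imputation_set"))
  qnames <- if ("name" %in% names(qtl)) as.character(qtl$name) else
    paste0("Q", seq_len(nrow(qtl)))
  idx <- .snap_positions(imps, qtl)
  base <- lapply(seq_len(imps$M), function(m) {
    X <- .model_design(imps, idx, interactions, m, qnames)$X
    sweep(X, 2, colMeans(X))
  })
  lod <- .scan_core(imps, phenotype, seq_len(nrow(imps$grid)),
                    base_cols = function(m) base[[m]])
  new_lod_profile(imps$grid, drop(lod), method = "addqtl")
}

#' Two-dimensional scan for epistatic QTL
#'
#' For every pair of (coarsened) grid positions, fits the full model
#' (two loci plus their interaction cross-products) and the additive
#' model (two loci only); both LODs are against the no-QTL null and the
#' interaction LOD is their difference.
#'
#' @inheritParams fit_qtl_model
#' @param step Coarsening step in cM (default 5) bounding the grid.
#' @return Object of class `scan_two`: data frame of position pairs with
#'   `lod_full`, `lod_add`, `lod_int`.
#' @export
scan_two <- function(imps, phenotype, step = 5) {
  stopifnot(inherits(imps, "imputation_set"))
  y <- as.numeric(phenotype)
  n <- length(y)
  yc <- y - mean(y)
  css <- sum(yc^2)
  if (css == 0) stop("zero phenotypic variance")
  keep <- unlist(lapply(unique(imps$grid$chr), function(cc) {
    on <- which(imps$grid$chr == cc)
    want <- seq(min(imps$grid$pos[on]), max(imps$grid$pos[on]), by = step)
    unique(on[vapply(want, function(w) which.min(abs(imps$grid$pos[on] - w)), 0L)])
  }))
  pairs <- utils::combn(keep, 2)
  np <- ncol(pairs)
  lf <- matrix(0, imps$M, np)
  la <- matrix(0, imps$M, np)
  for (m in seq_len(imps$M)) {
    Xs <- lapply(keep, function(p) {
      X <- .qtl_cols(imps, p, m)
      sweep(X, 2, colMeans(X))
    })
    names(Xs) <- as.character(keep)
    for (k in seq_len(np)) {
      X1 <- Xs[[as.character(pairs[1, k])]]
      X2 <- Xs[[as.character(pairs[2, k])]]
      prods <- do.call(cbind, lapply(seq_len(ncol(X1)),
                                     function(ci) X1[, ci] * X2))
      prods <- sweep(prods, 2, colMeans(prods))
      rss_add <- .rss_reduce(cbind(X1, X2), yc, css)
      rss_full <- .rss_reduce(cbind(X1, X2, prods), yc, css)
      la[m, k] <- (n / 2) * (log10(css) - log10(pmax(rss_add, 1e-300)))
      lf[m, k] <- (n / 2) * (log10(css) - log10(pmax(rss_full, 1e-300)))
    }
  }
  lod_full <- .combine_lod(lf)
  lod_add <- .combine_lod(la)
  out <- data.frame(chr1 = imps$grid$chr[pairs[1, ]],
                    pos1 = imps$grid$pos[pairs[1, ]],
                    chr2 = imps$grid$chr[pairs[2, ]],
                    pos2 = imps$grid$pos[pairs[2, ]],
                    lod_full = lod_full, lod_add = lod_add,
                    lod_int = lod_full - lod_add,
                    stringsAsFactors = FALSE)
  structure(out, step = step, class = c("scan_two", "data.frame"))
}

#' @export
print.scan_two <- function(x, ...) {
  cat("Two-dimensional scan:", nrow(x), "position pairs (step",
      attr(x, "step"), "cM)\n")
  pk <- x[which.max(x$lod_int), ]
  cat(sprintf("  max interaction LOD %.2f at %s@%.1f x %s@%.1f\n",
              pk$lod_int, pk$chr1, pk$pos1, pk$chr2, pk$pos2))
  invisible(x)
}

#' LOD support interval around a scan peak
#'
#' The maximal contiguous run of grid positions containing the peak on
#' which the LOD stays within `drop` of the peak LOD (the conventional
#' 2-LOD support interval when `drop = 2`).
#'
#' @param profile A `lod_profile`.
#' @param chr Chromosome of the peak.
#' @param pos Peak position in cM (default: the chromosome's maximum).
#' @param drop LOD drop defining the interval (default 2).
#' @return One-row data frame (`chr`, `peak`, `peak_lod`, `lower`,
#'   `upper`, `drop`, `whole_chromosome`); the flag marks a profile that
#'   never falls below `peak - drop` on one side.
#' @export
lod_support_interval <- function(profile, chr, pos = NULL, drop = 2) {
  d <- profile[profile$chr == as.character(chr), ]
  if (!nrow(d)) stop("no positions on chromosome ", chr)
  d <- d[order(d$pos), ]
  pk <- if (is.null(pos)) which.max(d$lod) else which.min(abs(d$pos - pos))
  thr <- d$lod[pk] - drop
  lo <- pk
  while (lo > 1 && d$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < nrow(d) && d$lod[hi + 1] >= thr) hi <- hi + 1
  data.frame(chr = as.character(chr), peak = d$pos[pk], peak_lod = d$lod[pk],
              lower = d$pos[lo], upper = d$pos[hi], drop = drop,
              whole_chromosome = (lo == 1 && hi == nrow(d)),
              stringsAsFactors = FALSE)
}
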