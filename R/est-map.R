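# Genetic-map re-estimation from marker genotypes.  Adjacent-pair
# recombination fractions are estimated by maximum likelihood for an
# intercross (EM over the unobserved two-locus gamete configurations;
# individuals missing either marker drop out of the pairwise likelihood,
# which is exact marginalization because the single-marker term does not
# depend on r), then converted to cM with the inverse Haldane function
# d = -50 log(1 - 2r).  Hemizygous male X genotypes expose single meioses,
# so the X recombination fraction is a direct count.  Marker order is
# taken from the input map and never revisited.

# genotype -> count of B alleles (0/1/2; hemizygous 0/1)
.b_count <- function(g) {
  unname(c(AA = 0L, AB = 1L, BB = 2L, A = 0L, B = 1L)[g])
}

# 16 ordered two-locus gamete pairs for the EM: gamete alleles at locus 1
# and 2, and whether each gamete is recombinant
.gam <- local({
  g <- expand.grid(a1 = 0:1, a2 = 0:1)        # 4 gamete haplotypes
  rec <- as.integer(g$a1 != g$a2)
  pair <- expand.grid(u = 1:4, v = 1:4)
  list(u = pair$u, v = pair$v,
       cls = (g$a1[pair$u] + g$a1[pair$v]) * 3 + (g$a2[pair$u] + g$a2[pair$v]) + 1,
       rec = rec[pair$u] + rec[pair$v],
       hap_rec = rec)
})

# EM estimate of r from two autosomal intercross marker columns
# (B-allele counts 0/1/2, NAs allowed)
em_rf_f2 <- function(g1, g2, tol = 1e-10, maxit = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  cls <- g1[ok] * 3 + g2[ok] + 1
  cnt <- tabulate(cls, 9)
  n <- sum(cnt)
  r <- 0.2
  for (it in seq_len(maxit)) {
    p <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
    w <- p[.gam$u] * p[.gam$v]
    pc <- vapply(1:9, function(k) sum(w[.gam$cls == k]), 0)
    ec <- vapply(1:9, function(k) sum((w * .gam$rec)[.gam$cls == k]), 0)
    e <- ifelse(pc > 0, ec / pc, 0)
    rnew <- sum(cnt * e) / (2 * n)
    if (abs(rnew - r) < tol) { r <- rnew; break }
    r <- rnew
  }
  r
}

# direct ML recombination fraction from hemizygous male X genotypes
rf_x_male <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  mean(g1[ok] != g2[ok])
}

#' Re-estimate a genetic map from marker genotypes
#'
#' @param pop A `cross_pop` (or any object with a `geno` character matrix
#'   and a `map`).
#' @param map Marker map fixing order and chromosome assignment; default
#'   the population's own map.
#' @return A `genmap` on the estimated scale, first marker of each
#'   chromosome at 0 cM.  Adjacent fractions >= 0.5 are capped at 0.49
#'   with a warning; pairs with no informative individuals keep their
#'   input distance (with a warning).
#' @export
estimate_map <- function(pop, map = pop$map) {
  map <- validate_genmap(map)
  geno <- pop$geno[, map$marker, drop = FALSE]
  capped <- FALSE
  est <- lapply(unique(map$chr), function(cc) {
    sel <- which(map$chr == cc)
    pos <- numeric(length(sel))
    if (length(sel) > 1) {
      for (i in seq_len(length(sel) - 1)) {
        g1 <- .b_count(geno[, sel[i]])
        g2 <- .b_count(geno[, sel[i + 1]])
        r <- if (cc == "X") rf_x_male(g1, g2) else em_rf_f2(g1, g2)
        if (is.na(r)) {
          warning("no informative pairs for markers ", map$marker[sel[i]],
                  " / ", map$marker[sel[i + 1]], "; keeping input distance")
          d <- map$pos[sel[i + 1]] - map$pos[sel[i]]
        } else {
          if (r >= 0.5) { r <- 0.49; capped <<- TRUE }
          d <- haldane_d(r)
        }
        pos[i + 1] <- pos[i] + d
      }
    }
    data.frame(marker = map$marker[sel], chr = cc, arm = map$arm[sel],
               pos = pos, stringsAsFactors = FALSE)
  })
  if (capped) warning("adjacent recombination fraction(s) >= 0.5 capped at 0.49")
  est <- do.call(rbind, est)
  chr_len <- tapply(est$pos, est$chr, max)
  out <- structure(est,
                   chr_len = stats::setNames(as.numeric(chr_len), names(chr_len)),
                   estimated = TRUE, class = c("genmap", "data.frame"))
  rownames(out) <- NULL
  out
}
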