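# Shared fixtures and small geometry/statistics helpers, all built in
# code at test time.

# distance from a point to the closed polygon's boundary
pt_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

pt_poly_dist <- function(p, poly) {
  n <- nrow(poly)
  min(vapply(seq_len(n), function(i) {
    pt_seg_dist(p, poly[i, ], poly[if (i == n) 1 else i + 1, ])
  }, 0))
}

max_outline_dev <- function(pts, poly) {
  max(vapply(seq_len(nrow(pts)), function(i) pt_poly_dist(pts[i, ], poly), 0))
}

# one-arm autosomal test map
arm_map <- function(n_markers, length_cm = 50, arm = "2L") {
  make_marker_panel(stats::setNames(n_markers, arm),
                    arm_lengths = stats::setNames(length_cm, arm))
}

# hand-built population around a given genotype matrix (codes AA/AB/BB,
# hemizygous A/B on X, NA missing)
manual_pop <- function(geno, map, pheno = NULL, generation = 2L) {
  n <- nrow(geno)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(n))
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  ph <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(pheno)) for (nm in names(pheno)) ph[[nm]] <- pheno[[nm]]
  structure(list(geno = geno, map = map, sex = rep("M", n), pheno = ph,
                 genotyped = rowSums(!is.na(geno)) > 0,
                 generation = generation, haplotypes = NULL),
            class = "cross_pop")
}

# single-locus architecture at a map position
one_locus_arch <- function(chr, pos, a = 1, d = 0, residual_sd = 1,
                           lobe_cor = 0.85) {
  qtl_architecture(data.frame(chr = chr, pos = pos, a = a, d = d,
                              stringsAsFactors = FALSE),
                   residual_sd = residual_sd, lobe_cor = lobe_cor)
}

# imputations for a quick fully-typed scan
quick_imps <- function(pop, map = pop$map, step = 10, M = 4, seed = 99,
                       error_prob = 1e-4) {
  impute_genotypes(genotype_probabilities(pop, map, step = step,
                                          error_prob = error_prob),
                   M = M, seed = seed)
}

# 27-path enumeration oracle for a 3-marker autosomal chromosome:
# P(g1, g2, g3) = init(g1) T12(g1,g2) T23(g2,g3) x emissions
enumerate_posterior <- function(obs, d12, d23, eps, target = 2L) {
  init <- c(.25, .5, .25)
  T12 <- lobeqtl:::.trans_f2(haldane_r(d12))
  T23 <- lobeqtl:::.trans_f2(haldane_r(d23))
  emit <- function(o, g) {
    if (is.na(o)) return(1)
    if (o == g) 1 - eps else eps / 2
  }
  codes <- c("AA", "AB", "BB")
  w <- array(0, c(3, 3, 3))
  for (g1 in 1:3) for (g2 in 1:3) for (g3 in 1:3) {
    w[g1, g2, g3] <- init[g1] * T12[g1, g2] * T23[g2, g3] *
      emit(obs[1], codes[g1]) * emit(obs[2], codes[g2]) * emit(obs[3], codes[g3])
  }
  marg <- apply(w, target, sum)
  marg / sum(marg)
}

toy3 <- function(obs, d12 = 20, d23 = 35) {
  map <- make_marker_panel(c("2L" = 3), arm_lengths = c("2L" = 60),
                           positions = list("2L" = c(0, d12, d12 + d23)))
  manual_pop(matrix(obs, 2, 3, byrow = TRUE,
                    dimnames = list(NULL, map$marker)), map)
}

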