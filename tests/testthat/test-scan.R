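scan_fixture <- function(n = 150, seed = 81, a = 1, d = 0, qtl_pos = 20,
                         arch_sd = 1, map = arm_map(4, 45)) {
  pop <- simulate_cross(cross_design(2, n_males = n), map, seed = seed)
  arch <- one_locus_arch("2", qtl_pos, a = a, d = d, residual_sd = arch_sd)
  assign_phenotypes(pop, arch, seed = seed + 1)
}

test_that("combined LOD at a fully typed marker equals the regression LOD", {
  pop <- scan_fixture()
  imps <- quick_imps(pop, step = 15, M = 8, error_prob = 0)
  y <- pop$pheno$score
  prof <- interval_mapping(imps, y)
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  for (j in seq_len(nrow(pop$map))) {
    xz <- lobeqtl:::geno_xz(pop$geno[, j])
    rss1 <- sum(stats::lm.fit(cbind(1, xz$x, xz$z), y)$residuals^2)
    lod_cf <- (n / 2) * log10(rss0 / rss1)
    lod_scan <- prof$lod[prof$pos == pop$map$pos[j]]
    expect_lt(abs(lod_scan - lod_cf), 1e-6)
  }
})

test_that("LOD is invariant to affine phenotype transforms", {
  pop <- scan_fixture(seed = 82)
  imps <- quick_imps(pop, step = 10, M = 6)
  p1 <- interval_mapping(imps, pop$pheno$score)
  p2 <- interval_mapping(imps, -2.5 * pop$pheno$score + 7)
  expect_lt(max(abs(p1$lod - p2$lod)), 1e-9)
})

test_that("profiles are nonnegative, finite, and error on constant phenotypes", {
  pop <- scan_fixture(seed = 83, a = 0)
  imps <- quick_imps(pop, step = 10, M = 4)
  prof <- interval_mapping(imps, pop$pheno$score)
  expect_true(all(prof$lod >= -1e-9))
  expect_true(all(is.finite(prof$lod)))
  expect_error(interval_mapping(imps, rep(1, nrow(pop$geno))), "variance")
  expect_error(interval_mapping(imps, pop$pheno$score[-1]), "length")
})

test_that("CIM with zero covariates reduces to interval mapping", {
  pop <- scan_fixture(seed = 84)
  imps <- quick_imps(pop, step = 10, M = 4)
  im <- interval_mapping(imps, pop$pheno$score)
  cim0 <- composite_interval_mapping(imps, pop$pheno$score, n_covariates = 0)
  expect_lt(max(abs(im$lod - cim0$lod)), 1e-9)
})

test_that("CIM drops covariates inside the window around the test position", {
  pop <- scan_fixture(seed = 85, a = 1.5)
  imps <- quick_imps(pop, step = 5, M = 4)
  cim <- composite_interval_mapping(imps, pop$pheno$score, window = 10,
                                    n_covariates = 2)
  cov_tab <- attr(cim, "covariates")
  active <- attr(cim, "cov_active")
  expect_equal(nrow(cov_tab), 2)
  for (p in seq_len(nrow(cim))) {
    near <- cov_tab$marker[abs(cov_tab$pos - cim$pos[p]) <= 5 &
                           cov_tab$chr == cim$chr[p]]
    expect_true(all(!near %in% active[[p]]))
    far <- setdiff(cov_tab$marker, near)
    expect_true(all(far %in% active[[p]]))
  }
  # a covariate coincident with its own test position is excluded there
  for (i in seq_len(nrow(cov_tab))) {
    at <- which(cim$pos == cov_tab$pos[i])
    expect_false(cov_tab$marker[i] %in% active[[at]])
  }
  expect_error(composite_interval_mapping(imps, pop$pheno$score,
                                          n_covariates = 4), "smaller")
})

test_that("CIM lowers the valley between two linked QTL relative to IM", {
  map <- arm_map(7, 60)
  diffs <- vapply(1:10, function(rep) {
    pop <- simulate_cross(cross_design(2, n_males = 200), map,
                          seed = 860 + rep)
    arch <- qtl_architecture(
      data.frame(chr = "2", pos = c(15, 45), a = c(1.2, 1.2), d = c(0, 0)),
      residual_sd = 1)
    pop <- assign_phenotypes(pop, arch, seed = 870 + rep)
    imps <- quick_imps(pop, step = 5, M = 4, seed = rep)
    y <- pop$pheno$score
    im <- interval_mapping(imps, y)
    cim <- composite_interval_mapping(imps, y, window = 10, n_covariates = 3)
    mid <- which.min(abs(im$pos - 30))
    cim$lod[mid] - im$lod[mid]
  }, 0)
  expect_lt(stats::median(diffs), 0)
})

test_that("unmasking genotypes does not reduce power at a true QTL", {
  map <- arm_map(4, 45)
  gains <- vapply(1:10, function(rep) {
    pop <- simulate_cross(cross_design(2, n_males = 120), map,
                          seed = 880 + rep)
    pop <- assign_phenotypes(pop, one_locus_arch("2", 20, a = 0.8),
                             seed = 890 + rep)
    masked <- pop
    masked$geno[seq(1, 120, by = 2), ] <- NA
    y <- pop$pheno$score
    full <- interval_mapping(quick_imps(pop, step = 15, M = 6, seed = rep), y)
    part <- interval_mapping(quick_imps(masked, step = 15, M = 6, seed = rep), y)
    at <- which.min(abs(full$pos - 20))
    full$lod[at] - part$lod[at]
  }, 0)
  expect_gt(mean(gains), 0)
})
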