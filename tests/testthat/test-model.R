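test_that("single-locus fit recovers a, d and the F2 variance identity", {
  map <- arm_map(3, 40)
  fits <- lapply(1:5, function(rep) {
    pop <- simulate_cross(cross_design(2, n_males = 5000), map,
                          seed = 1010 + rep)
    pop <- assign_phenotypes(pop, one_locus_arch("2", 20, a = 1, d = 0),
                             seed = 1020 + rep)
    imps <- quick_imps(pop, step = 20, M = 4, seed = rep)
    fit_qtl_model(imps, pop$pheno$score, data.frame(chr = "2", pos = 20))
  })
  a_hat <- mean(vapply(fits, function(f) f$qtl$a, 0))
  d_hat <- mean(vapply(fits, function(f) f$qtl$d, 0))
  pct <- mean(vapply(fits, function(f) f$total_pct_var, 0))
  expect_lt(abs(a_hat - 1), 0.05)
  expect_true(all(vapply(fits, function(f) f$qtl$a, 0) > 0))  # Sam allele raises the score
  expect_lt(abs(d_hat - 0), 0.05)
  # expected fraction: (a^2/2) / (a^2/2 + sd^2) = 1/3
  expect_lt(abs(pct - 100 / 3), 1)
  expect_lt(abs(mean(vapply(fits, function(f) f$qtl$pct_var, 0)) - 100 / 3), 1)
})

test_that("a generative null interaction fits near zero", {
  map <- arm_map(5, 80)
  pop <- simulate_cross(cross_design(2, n_males = 5000), map, seed = 103)
  arch <- qtl_architecture(
    data.frame(chr = "2", pos = c(20, 60), a = c(1, 1), d = c(0, 0)),
    residual_sd = 1)
  pop <- assign_phenotypes(pop, arch, seed = 104)
  imps <- quick_imps(pop, step = 20, M = 4)
  fit <- fit_qtl_model(imps, pop$pheno$score,
                       data.frame(chr = c("2", "2"), pos = c(20, 60)),
                       interactions = list(c(1L, 2L)))
  expect_lt(fit$interactions$pct_var, 1)
})

test_that("model nesting is monotone in total variance explained", {
  map <- arm_map(4, 60)
  pop <- simulate_cross(cross_design(2, n_males = 300), map, seed = 105)
  arch <- qtl_architecture(
    data.frame(chr = "2", pos = c(20, 40), a = c(1, 0.5), d = c(0.3, 0)),
    residual_sd = 1)
  pop <- assign_phenotypes(pop, arch, seed = 106)
  imps <- quick_imps(pop, step = 20, M = 4)
  y <- pop$pheno$score
  small <- fit_qtl_model(imps, y, data.frame(chr = "2", pos = 20))
  big <- fit_qtl_model(imps, y, data.frame(chr = c("2", "2"), pos = c(20, 40)),
                       interactions = list(c(1L, 2L)))
  expect_lte(small$total_pct_var, big$total_pct_var + 1e-9)
  expect_true(all(small$qtl$pct_var >= -1e-9))
  expect_true(all(big$qtl$pct_var >= -1e-9))
  expect_error(fit_qtl_model(imps, y,
                             data.frame(chr = c("2", "2"), pos = c(20, 21))),
               "collinear")
})

test_that("addqtl scan is flat at modeled loci and finds omitted ones", {
  map <- arm_map(5, 80)
  hits <- 0L
  for (rep in 1:8) {
    pop <- simulate_cross(cross_design(2, n_males = 250), map,
                          seed = 1070 + rep)
    arch <- qtl_architecture(
      data.frame(chr = "2", pos = c(20, 60), a = c(1, 1), d = c(0, 0)),
      residual_sd = 1)
    pop <- assign_phenotypes(pop, arch, seed = 1080 + rep)
    imps <- quick_imps(pop, step = 5, M = 4, seed = rep)
    y <- pop$pheno$score
    prof <- scan_additional(imps, y, data.frame(chr = "2", pos = 20))
    at_modeled <- prof$lod[which.min(abs(prof$pos - 20))]
    expect_lt(at_modeled, 0.5)
    si <- lod_support_interval(prof, "2", prof$pos[which.max(prof$lod)])
    if (si$lower <= 60 && si$upper >= 60) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("scan_two separates additive from epistatic architectures", {
  map <- arm_map(5, 80)
  pop <- simulate_cross(cross_design(2, n_males = 400), map, seed = 109)
  # pure additive pair
  arch_add <- qtl_architecture(
    data.frame(chr = "2", pos = c(20, 60), a = c(1, 1), d = c(0, 0)),
    residual_sd = 1)
  pop_a <- assign_phenotypes(pop, arch_add, seed = 110)
  imps <- quick_imps(pop_a, step = 10, M = 4)
  st_a <- scan_two(imps, pop_a$pheno$score, step = 10)
  expect_true(all(st_a$lod_int >= -1e-9))
  expect_true(all(st_a$lod_int <= st_a$lod_full + 1e-9))
  # strong epistasis: increment only for the double-B-homozygote,
  # i.e. equal aa/ad/da/dd cross-terms on top of matched main effects
  arch_epi <- qtl_architecture(
    data.frame(chr = "2", pos = c(20, 60), a = c(.5, .5), d = c(.25, .25)),
    interactions = list(list(pair = c(1L, 2L),
                             coef = c(1, 1, 1, 1) * 0.9)),
    residual_sd = 1)
  pop_e <- assign_phenotypes(pop, arch_epi, seed = 111)
  imps_e <- quick_imps(pop_e, step = 10, M = 4)
  st_e <- scan_two(imps_e, pop_e$pheno$score, step = 10)
  pk <- st_e[which.max(st_e$lod_int), ]
  expect_gt(pk$lod_int, max(st_a$lod_int))
  expect_lt(abs(pk$pos1 - 20), 15)
  expect_lt(abs(pk$pos2 - 60), 15)
})

test_that("support intervals follow the LOD-drop geometry", {
  grid <- data.frame(chr = "2", pos = 0:20,
                     lod = pmax(10 - abs(0:20 - 10), 0))
  prof <- structure(grid, class = c("lod_profile", "data.frame"))
  si <- lod_support_interval(prof, "2", 10, drop = 2)
  expect_equal(c(si$lower, si$upper), c(8, 12))
  expect_false(si$whole_chromosome)
  flat <- structure(data.frame(chr = "2", pos = 0:20, lod = 5),
                    class = c("lod_profile", "data.frame"))
  sf <- lod_support_interval(flat, "2", 10, drop = 2)
  expect_equal(c(sf$lower, sf$upper), c(0, 20))
  expect_true(sf$whole_chromosome)
})

test_that("fitting only the genotyped tails inflates variance estimates", {
  # conditioning the analysis on the phenotypic extremes (rather than
  # keeping all phenotyped individuals with missing genotypes) biases
  # the explained-variance estimate upward
  map <- arm_map(4, 60)
  arch <- one_locus_arch("2", 30, a = 0.7, d = 0, residual_sd = 1)
  gen_pct <- 100 * (0.7^2 / 2) / (0.7^2 / 2 + 1)
  fits <- vapply(1:12, function(rep) {
    pop <- simulate_cross(cross_design(2, n_males = 150), map,
                          seed = 1120 + rep)
    pop <- assign_phenotypes(pop, arch, seed = 1130 + rep)
    pop <- select_tails(pop, k = 20)
    keep <- which(pop$genotyped)
    tails <- manual_pop(pop$geno[keep, , drop = FALSE], map,
                        pheno = list(score = pop$pheno$score[keep]))
    imps <- quick_imps(tails, step = 30, M = 8, seed = rep)
    fit_qtl_model(imps, tails$pheno$score,
                  data.frame(chr = "2", pos = 30))$total_pct_var
  }, 0)
  expect_gt(stats::median(fits), gen_pct)
})
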