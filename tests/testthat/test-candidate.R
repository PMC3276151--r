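toy_profile <- function(lods, chr = "2", pos = seq_along(lods) * 10) {
  structure(data.frame(chr = chr, pos = pos, lod = lods,
                       stringsAsFactors = FALSE),
            method = "im", class = c("lod_profile", "data.frame"))
}

test_that("a constant profile gives a degenerate null and p = 1", {
  prof <- toy_profile(rep(1.5, 12))
  cand <- data.frame(chr = "2", pos = c(20, 50, 90))
  res <- candidate_resampling_test(prof, cand, N = 500, seed = 1)
  expect_equal(res$observed, 3 * 1.5)
  expect_equal(res$null_mean, 3 * 1.5)
  expect_equal(res$null_sd, 0)
  expect_equal(res$p, 1)
})

test_that("empirical p matches exhaustive enumeration on a 10-position toy", {
  set.seed(99)
  lods <- sort(runif(10, 0, 5))  # distinct values
  prof <- toy_profile(lods)
  # candidates at the two largest LODs
  cand <- data.frame(chr = "2", pos = c(90, 100))
  obs <- sum(lods[9:10])
  pairs <- utils::combn(10, 2)
  exact <- mean(colSums(matrix(lods[pairs], 2)) >= obs)
  res <- candidate_resampling_test(prof, cand, N = 1e5, seed = 7)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(res$p - exact), 3 * se + 2 / 1e5)
  # null mean converges to k x grid mean
  expect_lt(abs(res$null_mean - 2 * mean(lods)),
            3 * res$null_sd / sqrt(1e5) * sqrt(2))
})

test_that("p is invariant to adding a constant to the profile", {
  set.seed(5)
  lods <- runif(15, 0, 3)
  cand <- data.frame(chr = "2", pos = c(30, 80, 120))
  r1 <- candidate_resampling_test(toy_profile(lods), cand, N = 2e4, seed = 11)
  r2 <- candidate_resampling_test(toy_profile(lods + 4), cand, N = 2e4,
                                  seed = 11)
  expect_equal(r1$p, r2$p)
  expect_equal(r2$observed - r1$observed, 3 * 4)
})

test_that("X positions are excluded and the study defaults are recorded", {
  set.seed(6)
  prof <- structure(
    data.frame(chr = rep(c("X", "2", "3"), each = 20),
               pos = rep(seq(5, 100, 5), 3),
               lod = runif(60, 0, 3), stringsAsFactors = FALSE),
    class = c("lod_profile", "data.frame"))
  cand <- synthetic_candidates()
  expect_equal(nrow(cand), 22)
  expect_equal(sum(cand$chr != "X"), 18)
  expect_message(
    res <- candidate_resampling_test(prof, cand, N = 5000, seed = 2),
    "X-linked")
  expect_equal(res$k, 18)
  expect_equal(res$N, 5000)
  expect_equal(res$seed, 2)
  # reproducible under a fixed seed
  res2 <- suppressMessages(
    candidate_resampling_test(prof, cand, N = 5000, seed = 2))
  expect_equal(res$p, res2$p)
  expect_error(candidate_resampling_test(toy_profile(runif(5)),
                                         data.frame(chr = "2",
                                                    pos = 1:6 * 5),
                                         N = 10), "more candidates")
})

test_that("cM-uniform sampling is available and weights sparse regions", {
  # grid dense on [10, 50], one distant point at 150 covering a huge span
  prof <- toy_profile(c(rep(0, 9), 10), pos = c(seq(10, 50, 5), 150))
  cand <- data.frame(chr = "2", pos = 150)
  r_grid <- candidate_resampling_test(prof, cand, N = 4000, seed = 3,
                                      unit = "grid")
  r_cm <- candidate_resampling_test(prof, cand, N = 4000, seed = 3,
                                    unit = "cm")
  # under cM sampling the isolated high-LOD point is drawn far more often,
  # so the observed sum is less surprising
  expect_gt(r_cm$p, r_grid$p)
})
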