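test_that("GLCM counts match exhaustive pair enumeration", {
  set.seed(7)
  for (rep in 1:6) {
    L <- sample(2:8, 1)
    p <- random_level_patch(6, 6, L = L, seed = 100 + rep)
    for (d in 1:5) {
      for (th in c(0, 45, 90, 135)) {
        for (sym in c(TRUE, FALSE)) {
          g <- compute_glcm(p, d, th, symmetric = sym)
          expect_identical(g$counts,
                           brute_glcm_counts(p$pixels, L, d, th, sym))
          expect_equal(sum(g$probs), 1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("analytic GLCMs: constant patch and alternating row", {
  const <- gray_image(matrix(2L, 4, 4), levels = 8, normalized = FALSE)
  g <- compute_glcm(const, 1, 0)
  expect_equal(g$probs[3, 3], 1)
  expect_equal(sum(g$probs), 1)
  alt <- gray_image(matrix(c(0L, 1L, 0L, 1L, 0L, 1L), nrow = 1),
                    levels = 2, normalized = FALSE)
  ga <- compute_glcm(alt, 1, 0, symmetric = TRUE)
  expect_equal(ga$probs[1, 2], 0.5)
  expect_equal(ga$probs[2, 1], 0.5)
  expect_equal(ga$probs[1, 1] + ga$probs[2, 2], 0)
})

test_that("symmetric GLCMs equal their transpose with equal marginals", {
  for (s in 1:5) {
    p <- random_level_patch(6, 6, L = 4, seed = 200 + s)
    g <- compute_glcm(p, sample(1:3, 1), sample(c(0, 45, 90, 135), 1))
    expect_identical(g$counts, t(g$counts))
    expect_equal(g$mu_x, g$mu_y)
    expect_equal(g$sigma_x, g$sigma_y)
  }
})

test_that("offsets exceeding the patch extent raise an empty-GLCM error", {
  p <- random_level_patch(4, 4, L = 4, seed = 9)
  expect_error(compute_glcm(p, 4, 0), "empty GLCM")
  expect_error(compute_glcm(p, 4, 135), "empty GLCM")
  expect_silent(compute_glcm(p, 3, 90))
})

test_that("Haralick features hit their closed-form values", {
  # single-cell GLCM (constant patch): E=1, H=0, C=0, rho=1 by policy
  g1 <- glcm_from_counts(matrix(c(0, 0, 0, 4), 2, 2))
  h1 <- haralick_features(g1)
  expect_equal(unlist(h1), c(energy = 1, entropy = 0, correlation = 1,
                             contrast = 0))
  # two-cell symmetric GLCM: E=1/2, H=1 bit, C=1, rho=-1
  g2 <- glcm_from_counts(matrix(c(0, 1, 1, 0), 2, 2))
  h2 <- haralick_features(g2)
  expect_equal(unlist(h2), c(energy = 0.5, entropy = 1, correlation = -1,
                             contrast = 1))
  # uniform GLCM over 64 cells: E=1/64, H=6 bits, rho=0 (independence)
  g3 <- glcm_from_counts(matrix(1, 8, 8))
  h3 <- haralick_features(g3)
  expect_equal(h3$energy, 1 / 64)
  expect_equal(h3$entropy, 6)
  expect_equal(h3$correlation, 0)
  # k equal cells on the diagonal: entropy log2(k), energy 1/k
  g4 <- glcm_from_counts(diag(4))
  expect_equal(haralick_features(g4)$entropy, 2)
  expect_equal(haralick_features(g4)$energy, 0.25)
})

test_that("feature ranges respect their theoretical bounds", {
  for (s in 1:10) {
    p <- random_level_patch(6, 6, L = 8, seed = 300 + s)
    h <- haralick_features(compute_glcm(p, 1, 45))
    expect_true(h$energy > 0 && h$energy <= 1)
    expect_true(h$entropy >= 0 && h$entropy <= 2 * log2(8))
    expect_true(h$correlation >= -1 - 1e-12 && h$correlation <= 1 + 1e-12)
    expect_true(h$contrast >= 0 && h$contrast <= 49)
  }
})

test_that("aggregation averages per-combo features and skips empty combos", {
  p <- random_level_patch(6, 6, L = 8, seed = 11)
  agg <- aggregate_texture(p, distances = 1:5, per_combo = TRUE)
  per <- attr(agg, "per_combo")
  expect_equal(nrow(per), 20)
  expect_length(attr(agg, "skipped"), 0)
  # independent recomputation of the mean across all 20 combos
  manual <- sapply(c("energy", "entropy", "correlation", "contrast"),
                   function(f) {
    mean(sapply(seq_len(nrow(per)), function(k) {
      haralick_features(compute_glcm(p, per$d[k], per$theta[k]))[[f]]
    }))
  })
  expect_equal(unlist(agg[names(manual)]), manual, tolerance = 1e-12)
  # constant patch: every combo identical
  const <- gray_image(matrix(5L, 6, 6), levels = 8, normalized = FALSE)
  ac <- aggregate_texture(const)
  expect_equal(unlist(ac), c(energy = 1, entropy = 0, correlation = 1,
                             contrast = 0))
  # a 6x1 column admits only theta=90 combos; the rest are skipped
  col <- gray_image(matrix(0:5, ncol = 1), levels = 8, normalized = FALSE)
  acol <- aggregate_texture(col)
  expect_length(attr(acol, "skipped"), 15)
  expect_error(aggregate_texture(col, distances = 6:9), "every")
})

test_that("patches invariant under 90-degree rotation give equal 0/90 features", {
  # checkerboard is invariant under 90-degree rotation
  chk <- gray_image(outer(0:5, 0:5, function(a, b) (a + b) %% 2),
                    levels = 2, normalized = FALSE)
  f0 <- haralick_features(compute_glcm(chk, 1, 0))
  f90 <- haralick_features(compute_glcm(chk, 1, 90))
  expect_equal(unlist(f0), unlist(f90))
  both <- aggregate_texture(chk, distances = 1, angles = c(0, 90))
  expect_equal(unlist(both), unlist(f0))
})
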