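test_that("degenerate generator settings behave analytically", {
  const <- class_params(0.5, 0, corr_length = 0)
  img <- generate_image(const, 16, seed = 1)
  expect_true(all(img$pixels == 128))
  expect_equal(attr(img, "clip_fraction"), 0)
  # corr_length 0 is white noise: negligible neighbour correlation
  wn <- class_params(0.5, 0.1, corr_length = 0)
  g <- to_gray(generate_image(wn, 128, seed = 2))$pixels
  r_horiz <- cor(as.vector(g[, -1]), as.vector(g[, -ncol(g)]))
  expect_lt(abs(r_horiz), 0.05)
})

test_that("color casts are luma-neutral and tilt the channel balance", {
  p <- class_params(0.5, 0.05, corr_length = 2,
                    color_cast = c(1.2, 0.9, 0.8))
  expect_equal(sum(c(0.299, 0.587, 0.114) * p$color_cast), 1,
               tolerance = 1e-12)
  img <- generate_image(p, 32, seed = 3)
  ch_means <- apply(img$pixels, 3, mean)
  expect_gt(ch_means[1], ch_means[2])
  expect_gt(ch_means[2], ch_means[3])
  gray_mean <- mean(to_gray(img)$pixels)
  expect_equal(gray_mean, 0.5, tolerance = 0.02)
})

test_that("generated images recover their target moments", {
  # unclipped regime: mean and SD recovered essentially exactly
  prm0 <- class_params(0.5, 0.05, corr_length = 2)
  m0 <- s0 <- numeric(40)
  for (i in 1:40) {
    g <- to_gray(generate_image(prm0, 64, seed = 4000 + i))$pixels
    m0[i] <- mean(g); s0[i] <- sd(as.vector(g))
  }
  expect_lt(abs(mean(m0) - 0.5), 3 * sd(m0) / sqrt(40) + 0.003)
  expect_equal(mean(s0), 0.05, tolerance = 0.02)
  # default (heavy-tailed, mildly clipped) classes: means stay on
  # target; clipping shaves at most a few percent off the SD
  for (cl in c("nevus", "melanoma")) {
    prm <- synthetic_config(seed = 1)$params[[cl]]
    means <- sds <- numeric(60)
    for (i in 1:60) {
      g <- to_gray(generate_image(prm, 64, seed = 5000 + i))$pixels
      means[i] <- mean(g)
      sds[i] <- sd(as.vector(g))
    }
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - prm$mean_intensity), 3 * se + 0.003)
    expect_equal(mean(sds), prm$sd_intensity, tolerance = 0.08)
  }
})

test_that("the sinh-arcsinh shaping moves skewness and kurtosis as asked", {
  prm <- class_params(0.5, 0.1, skew_target = 1.2, kurt_target = 3,
                      corr_length = 0)
  set.seed(8)
  v <- as.vector(to_gray(generate_image(prm, 128, seed = 8))$pixels)
  f <- first_order_features(v)
  expect_gt(f$skewness, 0.5) # clearly right-skewed
  expect_gt(f$kurtosis, 1)   # clearly heavy-tailed
  sym <- class_params(0.5, 0.1, skew_target = 0, kurt_target = 0,
                      corr_length = 0)
  fs <- first_order_features(
    as.vector(to_gray(generate_image(sym, 128, seed = 9))$pixels))
  expect_lt(abs(fs$skewness), 0.2)
})

test_that("dataset generation is reproducible and manifest-complete", {
  cfg <- synthetic_config(n_images_per_class = 5, image_size = 16, seed = 3)
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  man <- attr(m1, "manifest")
  expect_equal(nrow(man), 10)
  expect_equal(as.integer(table(man$label)), c(5L, 5L))
  expect_true(all(file.exists(file.path(d1, man$path))))
  for (f in man$path) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e5),
                     readBin(file.path(d2, f), "raw", 1e5))
  }
})

test_that("longer correlation length lowers aggregated GLCM contrast", {
  contrast_at <- function(cl_len) {
    prm <- class_params(0.45, 0.14, corr_length = cl_len)
    vals <- numeric(50)
    for (i in 1:50) {
      img <- generate_image(prm, 48, seed = 900 + i)
      pats <- extract_patches(img, 2, size = 6, seed = i)
      vals[i] <- mean(vapply(pats, function(p) {
        aggregate_texture(quantize(p$gray, 8))$contrast
      }, numeric(1)))
    }
    mean(vals)
  }
  c0 <- contrast_at(0.5)
  c2 <- contrast_at(2)
  c5 <- contrast_at(5)
  expect_gt(c0, c2)
  expect_gt(c2, c5)
})

test_that("default classes differ detectably in mean intensity", {
  man <- tiny_manifest(n_per_class = 50, size = 32, seed = 44)
  ds <- extract_dataset(man, n_per_image = 10, seed = 44)
  cs <- class_summary(ds, "gray_mean")
  expect_lt(cs$p_value, 0.05)
  expect_gt(cs$mean[["nevus"]], cs$mean[["melanoma"]])
})
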