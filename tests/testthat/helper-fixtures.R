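# Shared fixtures and independent oracles used across test files.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# Random integer-leveled gray patch.
random_level_patch <- function(h, w, L, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:(L - 1), h * w, replace = TRUE), h, w),
             levels = L, normalized = FALSE)
}

# Random normalized gray patch.
random_norm_patch <- function(h, w, seed) {
  set.seed(seed)
  gray_image(matrix(runif(h * w), h, w), levels = 256L, normalized = TRUE)
}

# Random 8-bit RGB image.
random_rgb <- function(h, w, seed, id = "rand") {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)),
            id = id)
}

# A full-image patch object built by sampling the single admissible
# position of an image of exactly the patch size.
patch_of <- function(img) {
  extract_patches(img, n = 1, size = img$height, seed = 1)[[1]]
}

# Independent GLCM oracle: literal double loop over every pixel pair.
brute_glcm_counts <- function(P, L, d, theta, symmetric = TRUE) {
  offs <- list(`0` = c(d, 0), `45` = c(d, -d), `90` = c(0, -d),
               `135` = c(-d, -d))
  o <- offs[[as.character(theta)]]
  counts <- matrix(0L, L, L)
  H <- nrow(P); W <- ncol(P)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      x2 <- x + o[1]; y2 <- y + o[2]
      if (x2 >= 1 && x2 <= W && y2 >= 1 && y2 <= H) {
        i <- P[y, x] + 1L; j <- P[y2, x2] + 1L
        counts[i, j] <- counts[i, j] + 1L
        if (symmetric) counts[j, i] <- counts[j, i] + 1L
      }
    }
  }
  counts
}

# Independent first-order oracle: literal moment sums over the
# empirical distribution (each distinct value weighted by frequency).
brute_first_order <- function(v) {
  tab <- table(v)
  vals <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(v)
  mu <- sum(vals * p)
  s2 <- sum((vals - mu)^2 * p)
  list(mean = mu, variance = s2,
       skewness = if (s2 > 0) s2^-1.5 * sum((vals - mu)^3 * p) else 0,
       kurtosis = if (s2 > 0) s2^-2 * sum((vals - mu)^4 * p) - 3 else 0)
}

# Independent AUC oracle: concordant-pair fraction with ties as 1/2.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == "melanoma"]
  neg <- scores[labels == "nevus"]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Small synthetic feature dataset built directly (no images): two
# Gaussian blobs in feature space, `n_img` images per class with
# `n_patch` patches each.  Only every other feature is shifted, so the
# classes differ in feature *proportions* as well as overall level
# (a uniform shift is invisible to proportion-based learners).
blob_dataset <- function(n_img = 10, n_patch = 5, sep = 3, seed = 1) {
  set.seed(seed)
  fn <- feature_names()
  shifted <- seq_along(fn) %% 2 == 1
  rows <- list()
  for (cl in c("melanoma", "nevus")) {
    shift <- if (cl == "melanoma") sep else 0
    for (i in seq_len(n_img)) {
      id <- sprintf("%s_img%02d", cl, i)
      X <- matrix(rnorm(n_patch * length(fn)), n_patch)
      X[, shifted] <- X[, shifted] + shift
      colnames(X) <- fn
      rows[[id]] <- data.frame(image_id = id, label = cl,
                               x0 = seq_len(n_patch) - 1L, y0 = 0L, X,
                               check.names = FALSE)
    }
  }
  dermtex:::new_feature_dataset(
    do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

# Tiny on-disk synthetic image set; returns the manifest data.frame.
tiny_manifest <- function(n_per_class = 3, size = 32, seed = 1,
                          dir = tempfile("imgs")) {
  cfg <- synthetic_config(n_images_per_class = n_per_class,
                          image_size = size, seed = seed)
  read_manifest(generate_dataset(cfg, dir))
}
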