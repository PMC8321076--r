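test_that("confusion matrices count exactly with melanoma positive", {
  truth <- c(rep("melanoma", 269), rep("nevus", 231))
  cm <- confusion(truth, truth)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(269, 231, 0, 0))
  all_nevus <- confusion(truth, rep("nevus", 500))
  expect_equal(c(all_nevus$tp, all_nevus$fn, all_nevus$tn, all_nevus$fp),
               c(0, 269, 231, 0))
  expect_error(confusion(truth, truth[-1]), "equal length")
  expect_error(confusion(c("melanoma", "weird"), c("nevus", "nevus")),
               "melanoma")
})

test_that("metrics reproduce hand-computed ratios and identities", {
  m <- metrics(confusion_from_counts(tp = 261, fp = 5, tn = 226, fn = 8))
  expect_equal(m$sensitivity, 261 / 269)
  expect_equal(m$specificity, 226 / 231)
  expect_equal(m$accuracy, 487 / 500)
  expect_equal(m$precision[["melanoma"]], 261 / 266)
  expect_equal(m$fpr, 1 - m$specificity, tolerance = 1e-12)
  pm <- m$precision[["melanoma"]]; rm_ <- m$recall[["melanoma"]]
  expect_equal(m$f_score[["melanoma"]], 2 * pm * rm_ / (pm + rm_))
  perfect <- metrics(confusion_from_counts(50, 0, 50, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$f_score), c(1, 1))
  # zero-denominator metrics are NA markers, not zeros
  degenerate <- metrics(confusion_from_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.na(degenerate$precision[["melanoma"]]))
  expect_equal(degenerate$specificity, 1)
})

test_that("ROC sweep matches the pairwise-concordance oracle", {
  y <- c("melanoma", "melanoma", "melanoma", "nevus", "nevus", "nevus")
  s <- c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1)
  r <- roc_auc(y, s)
  expect_equal(r$auc, brute_auc(y, s), tolerance = 1e-12)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # perfect ordering and constant scores
  expect_equal(roc_auc(y, c(3, 2.5, 2, 1, 0.5, 0))$auc, 1)
  expect_equal(roc_auc(y, rep(1, 6))$auc, 0.5)
  expect_error(roc_auc(rep("melanoma", 3), 1:3), "both classes")
  # agreement with an independent ROC implementation
  set.seed(15)
  yl <- sample(c("melanoma", "nevus"), 80, replace = TRUE)
  sc <- round(rnorm(80), 1)
  expect_equal(roc_auc(yl, sc)$auc,
               as.numeric(suppressMessages(pROC::auc(pROC::roc(
                 yl == "melanoma", sc, quiet = TRUE,
                 levels = c(FALSE, TRUE), direction = "<")))),
               tolerance = 1e-12)
})

test_that("Mann-Whitney matches exact enumeration on a small case", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  # exact two-sided p by enumerating all C(6,3)=20 rank assignments
  ranks <- utils::combn(6, 3)
  u_of <- function(xr) sum(xr) - 3 * 4 / 2
  u_all <- apply(ranks, 2, u_of)
  p_exact <- mean(pmin(u_all, 9 - u_all) <= 0) # |U - 4.5| >= 4.5
  expect_equal(p_exact, 0.1)
  expect_equal(r$p_value, 0.1)
  same <- mann_whitney(1:10, 1:10)
  expect_equal(same$U, 50) # n1*n2/2 under full exchangeability
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # power: a one-sigma shift at n=500 is overwhelmingly detected
  set.seed(20)
  expect_lt(mann_whitney(rnorm(500, 1), rnorm(500))$p_value, 1e-3)
})

test_that("AUC equals the rank-sum probability interpretation", {
  set.seed(25)
  for (rep in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x <- round(rnorm(n1), sample(0:2, 1)) # rounding injects ties
    y <- round(rnorm(n2, 0.3), sample(0:2, 1))
    lab <- c(rep("melanoma", n1), rep("nevus", n2))
    auc <- roc_auc(lab, c(x, y))$auc
    expect_equal(auc, mann_whitney(x, y)$U / (n1 * n2), tolerance = 1e-9)
  }
})

test_that("class summaries report per-class moments and rank-test p", {
  ds <- blob_dataset(n_img = 20, n_patch = 10, sep = 1, seed = 30)
  cs <- class_summary(ds, "gray_mean")
  expect_named(cs$mean, c("melanoma", "nevus"))
  expect_equal(unname(cs$n), c(200L, 200L))
  expect_lt(cs$p_value, 0.05) # shifted feature is detected
  expect_length(cs$fivenum$melanoma, 5)
  expect_error(class_summary(ds, "not_a_feature"), "unknown feature")
  # constant feature: equal means, zero SD, p near 1
  ds$gray_mean <- 1
  cs2 <- class_summary(ds, "gray_mean")
  expect_equal(unname(cs2$mean), c(1, 1))
  expect_equal(unname(cs2$sd), c(0, 0))
  expect_gt(cs2$p_value, 0.9)
})

test_that("majority vote collapses patches to image-level labels", {
  ids <- rep(c("a", "b"), each = 5)
  truth <- rep(c("melanoma", "nevus"), each = 5)
  pred <- c(rep("melanoma", 4), "nevus", rep("nevus", 3), "melanoma",
            "melanoma")
  mv <- majority_vote(ids, pred, truth)
  expect_equal(mv$pred[mv$image_id == "a"], "melanoma")
  expect_equal(mv$pred[mv$image_id == "b"], "nevus")
  expect_equal(mv$label, c("melanoma", "nevus"))
})
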