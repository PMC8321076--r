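# Image-level train/test splitting, the 12-classifier zoo, and AUC
# ranking.  All learners run with library-default hyperparameters and
# fixed derived seeds; melanoma is the positive class throughout.
#
# Per-model preprocessing (fitted on the training split only):
#   z-score      : sgd_linear, knn, linear_svc, svc_rbf, logistic,
#                  bernoulli_nb (then binarized at 0, i.e. above/below
#                  the training mean)
#   min-max [0,1]: multinomial_nb (requires nonnegative inputs)
#   raw          : decision_tree, extra_trees, random_forest,
#                  gradient_boosting, gaussian_nb

#' Names of the twelve classifiers in the zoo
#' @return character vector of valid model names.
#' @export
zoo_model_names <- function() {
  c("sgd_linear", "gaussian_nb", "bernoulli_nb", "multinomial_nb",
    "decision_tree", "extra_trees", "random_forest", "gradient_boosting",
    "knn", "linear_svc", "svc_rbf", "logistic")
}

MODEL_SCALING <- c(
  sgd_linear = "zscore", gaussian_nb = "none", bernoulli_nb = "zscore",
  multinomial_nb = "minmax", decision_tree = "none", extra_trees = "none",
  random_forest = "none", gradient_boosting = "none", knn = "zscore",
  linear_svc = "zscore", svc_rbf = "zscore", logistic = "zscore"
)

#' Split a feature dataset at the image level
#'
#' Image ids are partitioned (stratified by class) so that every patch
#' of one image lands on exactly one side; sibling patches can never
#' leak across the split.  The per-class number of training images is
#' `round(train_fraction * n_images)`, clamped so both sides keep at
#' least one image per class.
#'
#' @param ds a `feature_dataset`.
#' @param train_fraction proportion of images used for training
#'   (default 0.75).
#' @param seed integer seed for the random partition.
#' @return list with elements `train` and `test` (both
#'   `feature_dataset`) and `train_ids`, `test_ids`.
#' @export
split_dataset <- function(ds, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(ds, "feature_dataset"),
            train_fraction > 0, train_fraction < 1)
  img_label <- unique(ds[, c("image_id", "label")])
  if (any(table(img_label$label) < 2)) {
    stop("split_dataset: need at least 2 images per class", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  # Largest-remainder allocation: per-class training counts start at
  # floor(fraction * n) and the classes with the largest fractional
  # parts are topped up until the total equals round(fraction * total),
  # keeping every class within one image of the global fraction.
  n_class <- vapply(CLASS_LEVELS, function(cl) {
    sum(img_label$label == cl)
  }, numeric(1))
  n_tr <- floor(train_fraction * n_class)
  extra <- round(train_fraction * sum(n_class)) - sum(n_tr)
  if (extra > 0) {
    top_up <- order(train_fraction * n_class - n_tr,
                    decreasing = TRUE)[seq_len(extra)]
    n_tr[top_up] <- n_tr[top_up] + 1
  }
  n_tr <- pmin(pmax(n_tr, 1), n_class - 1)
  train_ids <- character()
  for (cl in CLASS_LEVELS) {
    ids <- sort(img_label$image_id[img_label$label == cl])
    set.seed(derive_seed(seed, paste0("split:", cl)))
    train_ids <- c(train_ids, sample(ids, n_tr[[cl]]))
  }
  test_ids <- setdiff(img_label$image_id, train_ids)
  list(
    train = subset_dataset(ds, train_ids),
    test = subset_dataset(ds, test_ids),
    train_ids = sort(train_ids), test_ids = sort(test_ids)
  )
}

subset_dataset <- function(ds, ids) {
  out <- ds[ds$image_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_dataset", "data.frame")
  out
}

dataset_matrix <- function(ds) {
  as.matrix(ds[, feature_names(), drop = FALSE])
}

fit_scaler <- function(X, type) {
  switch(type,
    none = list(type = "none"),
    zscore = {
      mu <- colMeans(X)
      sd <- apply(X, 2, stats::sd)
      sd[sd == 0] <- 1
      list(type = "zscore", center = mu, scale = sd)
    },
    minmax = {
      lo <- apply(X, 2, min)
      hi <- apply(X, 2, max)
      rng <- hi - lo
      rng[rng == 0] <- 1
      list(type = "minmax", lo = lo, rng = rng)
    }
  )
}

apply_scaler <- function(X, sc) {
  switch(sc$type,
    none = X,
    zscore = sweep(sweep(X, 2, sc$center), 2, sc$scale, "/"),
    minmax = pmin(pmax(sweep(sweep(X, 2, sc$lo), 2, sc$rng, "/"), 0), 1)
  )
}

#' Train the classifier zoo
#'
#' Fits one model per requested name on the training split.  Feature
#' standardization (see the per-model table in the source header) is
#' fitted on the training rows only, so no test information reaches
#' any model.  Stochastic learners receive seeds derived from `seed`
#' and the model name, making refits bit-reproducible.
#'
#' @param train a `feature_dataset` containing both classes.
#' @param model_names subset of [zoo_model_names()] (default: all 12).
#' @param seed master integer seed.
#' @return named list of `fitted_model` objects.
#' @export
train_zoo <- function(train, model_names = zoo_model_names(), seed = 1L) {
  stopifnot(inherits(train, "feature_dataset"), nrow(train) > 0)
  unknown <- setdiff(model_names, zoo_model_names())
  if (length(unknown)) {
    stop(sprintf("train_zoo: unknown model name(s) %s; valid names: %s",
                 paste(unknown, collapse = ", "),
                 paste(zoo_model_names(), collapse = ", ")), call. = FALSE)
  }
  y <- droplevels(train$label)
  if (nlevels(y) < 2) {
    stop("train_zoo: training set must contain both classes", call. = FALSE)
  }
  y <- factor(as.character(train$label), levels = CLASS_LEVELS)
  X <- dataset_matrix(train)
  models <- lapply(model_names, function(nm) {
    sc <- fit_scaler(X, MODEL_SCALING[[nm]])
    fit_one_model(nm, apply_scaler(X, sc), y,
                  seed = derive_seed(seed, paste0("model:", nm)), scaler = sc)
  })
  names(models) <- model_names
  models
}

new_fitted_model <- function(name, state, scaler, score_type, seed) {
  structure(
    list(name = name, state = state, scaler = scaler,
         feature_names = feature_names(), score_type = score_type,
         seed = seed),
    class = "fitted_model"
  )
}

fit_one_model <- function(name, Xs, y, seed, scaler) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ypos <- as.numeric(y == POSITIVE_CLASS) # melanoma = 1
  state <- switch(name,
    sgd_linear = fit_sgd_hinge(Xs, ypos, seed = seed),
    gaussian_nb = e1071::naiveBayes(x = as.data.frame(Xs), y = y),
    bernoulli_nb = fit_bernoulli_nb(Xs > 0, y),
    multinomial_nb = fit_multinomial_nb(Xs, y),
    decision_tree = rpart::rpart(
      label ~ ., data = data.frame(label = y, Xs), method = "class"),
    extra_trees = ranger::ranger(
      x = Xs, y = y, num.trees = 500, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      probability = TRUE, num.threads = 1, seed = seed),
    random_forest = randomForest::randomForest(x = Xs, y = y, ntree = 500),
    gradient_boosting = xgboost::xgb.train(
      params = list(eta = 0.1, max_depth = 3,
                    objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(Xs, label = ypos, nthread = 1),
      nrounds = 100),
    knn = list(X = Xs, y = y, k = 5L),
    linear_svc = kernlab::ksvm(
      x = Xs, y = y, kernel = "vanilladot", C = 1, scaled = FALSE,
      kpar = list()),
    svc_rbf = e1071::svm(x = Xs, y = y, kernel = "radial", cost = 1,
                         scale = FALSE),
    logistic = {
      co <- suppressWarnings(
        stats::glm.fit(cbind(1, Xs), ypos,
                       family = stats::binomial())$coefficients)
      co[is.na(co)] <- 0 # aliased (exactly collinear) columns drop out
      co
    }
  )
  score_type <- if (name %in% c("sgd_linear", "linear_svc", "svc_rbf")) {
    "margin"
  } else "prob"
  fm <- new_fitted_model(name, state, scaler, score_type, seed)
  if (name %in% c("linear_svc", "svc_rbf")) {
    # Orient the decision margin so that larger means more
    # melanoma-like (library sign conventions differ).
    raw <- raw_margin(fm, Xs)
    if (mean(raw[ypos == 1]) < mean(raw[ypos == 0])) fm$flip <- TRUE
  }
  fm
}

# Linear SVM trained by stochastic gradient descent on the hinge loss
# with L2 penalty (the classic primal SGD solver for linear SVC-style
# models).  alpha is the regularization strength; the step size decays
# as 1/(alpha * t).
fit_sgd_hinge <- function(X, ypos, seed, alpha = 1e-4, epochs = 30L) {
  n <- nrow(X); p <- ncol(X)
  ysign <- ifelse(ypos == 1, 1, -1)
  w <- numeric(p); b <- 0
  set.seed(seed)
  t <- 1 / (alpha * 100) # t0 offset keeps early steps bounded
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      eta <- 1 / (alpha * t)
      m <- ysign[i] * (sum(w * X[i, ]) + b)
      w <- w * (1 - eta * alpha)
      if (m < 1) {
        w <- w + eta * ysign[i] * X[i, ]
        b <- b + eta * ysign[i]
      }
      t <- t + 1
    }
  }
  list(w = w, b = b)
}

# Bernoulli naive Bayes on binarized features with Laplace smoothing.
fit_bernoulli_nb <- function(Xb, y) {
  classes <- levels(y)
  theta <- sapply(classes, function(cl) {
    (colSums(Xb[y == cl, , drop = FALSE]) + 1) / (sum(y == cl) + 2)
  })
  list(theta = theta, log_prior = log(table(y) / length(y)))
}

# Multinomial naive Bayes on nonnegative (min-max scaled) features.
fit_multinomial_nb <- function(Xmm, y) {
  classes <- levels(y)
  theta <- sapply(classes, function(cl) {
    s <- colSums(Xmm[y == cl, , drop = FALSE]) + 1
    s / sum(s)
  })
  list(log_theta = log(theta), log_prior = log(table(y) / length(y)))
}

#' @importMethodsFrom kernlab predict
raw_margin <- function(model, Xs) {
  switch(model$name,
    sgd_linear = as.numeric(Xs %*% model$state$w + model$state$b),
    linear_svc = as.numeric(predict(model$state, Xs, type = "decision")),
    svc_rbf = {
      pr <- stats::predict(model$state, Xs, decision.values = TRUE)
      as.numeric(attr(pr, "decision.values"))
    }
  )
}

#' Continuous melanoma score of a fitted model on new data
#'
#' Probability of the melanoma class where the learner exposes one,
#' otherwise the (sign-oriented) decision margin.  Higher always means
#' more melanoma-like.
#'
#' @param model a `fitted_model` from [train_zoo()].
#' @param ds a `feature_dataset` (labels are ignored).
#' @return numeric vector, one score per patch row.
#' @export
predict_scores <- function(model, ds) {
  stopifnot(inherits(model, "fitted_model"), inherits(ds, "feature_dataset"))
  X <- dataset_matrix(ds)
  stopifnot(identical(colnames(X), model$feature_names))
  Xs <- apply_scaler(X, model$scaler)
  sc <- switch(model$name,
    sgd_linear = ,
    linear_svc = ,
    svc_rbf = {
      m <- raw_margin(model, Xs)
      if (isTRUE(model$flip)) -m else m
    },
    gaussian_nb = stats::predict(model$state, as.data.frame(Xs),
                                 type = "raw")[, POSITIVE_CLASS],
    bernoulli_nb = nb_posterior(
      model$state$theta, Xs > 0, model$state$log_prior, bernoulli = TRUE),
    multinomial_nb = nb_posterior(
      exp(model$state$log_theta), Xs, model$state$log_prior,
      bernoulli = FALSE),
    decision_tree = stats::predict(model$state, data.frame(Xs),
                                   type = "prob")[, POSITIVE_CLASS],
    extra_trees = stats::predict(model$state, data = Xs,
                                 num.threads = 1)$predictions[, POSITIVE_CLASS],
    random_forest = stats::predict(model$state, Xs,
                                   type = "prob")[, POSITIVE_CLASS],
    gradient_boosting = stats::predict(
      model$state, xgboost::xgb.DMatrix(Xs, nthread = 1)),
    knn = knn_scores(model, Xs),
    logistic = as.numeric(stats::plogis(cbind(1, Xs) %*% model$state))
  )
  as.numeric(sc)
}

nb_posterior <- function(theta_rowsarefeatures, X, log_prior,
                         bernoulli = FALSE) {
  # theta: features x classes; returns P(melanoma | x)
  classes <- colnames(theta_rowsarefeatures) %||% names(log_prior)
  ll <- sapply(seq_along(log_prior), function(ci) {
    th <- theta_rowsarefeatures[, ci]
    if (bernoulli) {
      X %*% log(th) + (1 - X) %*% log(1 - th) + log_prior[ci]
    } else {
      X %*% log(th) + log_prior[ci]
    }
  })
  colnames(ll) <- names(log_prior)
  m <- apply(ll, 1, max)
  post <- exp(ll - m) / rowSums(exp(ll - m))
  post[, POSITIVE_CLASS]
}

knn_scores <- function(model, Xs) {
  st <- model$state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$seed) # distance-tie votes stay deterministic
  pred <- class::knn(train = st$X, test = Xs, cl = st$y, k = st$k,
                     prob = TRUE)
  p <- attr(pred, "prob") # proportion of votes for the winning class
  ifelse(pred == POSITIVE_CLASS, p, 1 - p)
}

#' Hard class labels of a fitted model on new data
#'
#' Thresholds the continuous score at 0.5 for probability models and
#' at 0 for margin models.
#'
#' @inheritParams predict_scores
#' @return factor with levels melanoma, nevus.
#' @export
predict_labels <- function(model, ds) {
  sc <- predict_scores(model, ds)
  thr <- if (model$score_type == "prob") 0.5 else 0
  factor(ifelse(sc > thr, POSITIVE_CLASS, "nevus"), levels = CLASS_LEVELS)
}

#' Rank fitted models by test-set AUC
#'
#' Scores every model on the test split, computes the ROC AUC from the
#' continuous melanoma scores, and returns the models sorted by
#' descending AUC together with full confusion-matrix reports.
#'
#' @param models list of `fitted_model` objects ([train_zoo()]).
#' @param test a `feature_dataset` containing both classes.
#' @param k how many top models to flag (default 5).
#' @return object of class `model_ranking`: list with `entries` (a
#'   data.frame `name`, `auc`, `accuracy`, sorted by AUC descending,
#'   with a logical `top` column marking the best `k`), `reports`
#'   (named list of `classifier_report`s) and `k`.
#' @export
rank_by_auc <- function(models, test, k = 5L) {
  stopifnot(length(models) > 0, inherits(test, "feature_dataset"))
  if (length(unique(test$label)) < 2) {
    stop("rank_by_auc: test set must contain both classes", call. = FALSE)
  }
  rows <- list()
  reports <- list()
  for (m in models) {
    scores <- predict_scores(m, test)
    roc <- roc_auc(test$label, scores)
    rep <- classifier_report(test$label, predict_labels(m, test),
                             auc = roc$auc, name = m$name)
    rows[[m$name]] <- data.frame(name = m$name, auc = roc$auc,
                                 accuracy = rep$metrics$accuracy)
    reports[[m$name]] <- rep
  }
  entries <- do.call(rbind, rows)
  entries <- entries[order(-entries$auc, entries$name), , drop = FALSE]
  rownames(entries) <- NULL
  k <- min(k, nrow(entries))
  entries$top <- seq_len(nrow(entries)) <= k
  structure(list(entries = entries, reports = reports, k = k),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("<model_ranking: %d models, top %d flagged>\n",
              nrow(x$entries), x$k))
  print(transform(x$entries, auc = round(auc, 4),
                  accuracy = round(accuracy, 4)))
  invisible(x)
}

#' Save / load a fitted model artifact
#'
#' Serializes the model (name, opaque state, scaler and feature order)
#' with `saveRDS`.
#'
#' @param model a `fitted_model`.
#' @param path artifact path (`.rds`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "fitted_model"))
  m
}
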