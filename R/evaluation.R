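# Confusion-matrix metrics, ROC/AUC, the Mann-Whitney rank test, and
# per-class feature summaries.  Melanoma is the positive class: TP are
# melanomas called melanoma, TN are nevi called nevus.

as_class_factor <- function(y) {
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (anyNA(y)) {
    stop("labels must be 'melanoma' or 'nevus'", call. = FALSE)
  }
  y
}

#' Confusion matrix of a binary melanoma/nevus prediction
#'
#' @param y_true,y_pred equal-length label vectors (values `melanoma`
#'   or `nevus`, character or factor).
#' @return object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn` and `total`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop("confusion: y_true and y_pred must be non-empty and equal length",
         call. = FALSE)
  }
  yt <- as_class_factor(y_true)
  yp <- as_class_factor(y_pred)
  confusion_from_counts(
    tp = sum(yt == "melanoma" & yp == "melanoma"),
    fn = sum(yt == "melanoma" & yp == "nevus"),
    tn = sum(yt == "nevus" & yp == "nevus"),
    fp = sum(yt == "nevus" & yp == "melanoma")
  )
}

#' Build a confusion matrix directly from its four counts
#'
#' @param tp,fp,tn,fn nonnegative counts; melanoma is positive.
#' @return a `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  structure(as.list(counts), total = sum(counts), class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (melanoma recall), specificity (nevus
#' recall), per-class precision and F-score, and the false-positive
#' rate `FP / (FP + TN)` (equal to 1 - specificity).  A metric whose
#' denominator is zero is reported as `NA` rather than 0, so undefined
#' values stay visibly undefined.
#'
#' @param cm a `confusion_matrix`.
#' @return object of class `metric_report` (a named list).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("metrics: empty confusion matrix", call. = FALSE)
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec_mel <- safe_ratio(tp, tp + fp)
  prec_nev <- safe_ratio(tn, tn + fn)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  }
  structure(
    list(
      accuracy = (tp + tn) / total,
      sensitivity = sens,
      specificity = spec,
      precision = c(melanoma = prec_mel, nevus = prec_nev),
      recall = c(melanoma = sens, nevus = spec),
      f_score = c(melanoma = f1(prec_mel, sens), nevus = f1(prec_nev, spec)),
      fpr = safe_ratio(fp, fp + tn),
      support = c(melanoma = tp + fn, nevus = tn + fp)
    ),
    class = "metric_report"
  )
}

#' ROC curve and AUC from continuous melanoma scores
#'
#' Sweeps a threshold over the unique score values (tied scores are
#' grouped into a single step) and accumulates (FPR, TPR) points from
#' (0, 0) to (1, 1); the AUC is the trapezoidal area under that path,
#' which counts tied positive/negative pairs as one half.
#'
#' @param y_true labels (`melanoma`/`nevus`), both classes present.
#' @param scores numeric scores, higher = more melanoma-like.
#' @return object of class `roc_curve` with `points` (data.frame
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  yt <- as_class_factor(y_true)
  if (length(scores) != length(yt)) {
    stop("roc_auc: labels and scores must have equal length", call. = FALSE)
  }
  n_pos <- sum(yt == "melanoma")
  n_neg <- sum(yt == "nevus")
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y_sorted <- yt[ord]
  s_sorted <- scores[ord]
  grp_last <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp_cum <- cumsum(y_sorted == "melanoma")[grp_last]
  fp_cum <- cumsum(y_sorted == "nevus")[grp_last]
  tpr <- c(0, tp_cum / n_pos)
  fpr <- c(0, fp_cum / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
    class = "roc_curve"
  )
}

#' Mann-Whitney U rank-sum test (two-sided)
#'
#' U counts the `(x, y)` pairs where `x` exceeds `y`, ties counting one
#' half.  The p-value is exact (by enumeration) when `n1 * n2 <= 200`
#' and the data are tie-free, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (e.g. a feature's values in melanoma and
#'   in nevus patches).
#' @return object of class `rank_test_result` with fields `U` and
#'   `p_value`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney: both samples must be non-empty", call. = FALSE)
  }
  exact <- (length(x) * length(y) <= 200) &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  # with every observation tied the normal approximation degenerates
  # (zero variance); exchangeability makes the two-sided p equal 1
  if (is.nan(p) || is.na(p)) p <- 1
  structure(
    list(U = unname(wt$statistic), p_value = min(p, 1)),
    class = "rank_test_result"
  )
}

#' Per-class summary of one feature with a rank test
#'
#' Mirrors a first-order statistics table row: per-class mean and
#' standard deviation plus the two-sided Mann-Whitney p-value for the
#' melanoma-vs-nevus comparison, and the per-class five-number summary
#' (boxplot support).
#'
#' @param ds a `feature_dataset` containing both classes.
#' @param feature one of [feature_names()].
#' @return list of class `class_summary` with `feature`, `mean`, `sd`
#'   (named by class), `p_value` and `fivenum` (list of length-5
#'   vectors per class).
#' @export
class_summary <- function(ds, feature) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (!feature %in% feature_names()) {
    stop(sprintf("class_summary: unknown feature '%s'", feature),
         call. = FALSE)
  }
  v <- split(ds[[feature]], ds$label)
  if (any(lengths(v) == 0)) {
    stop("class_summary: both classes must be present", call. = FALSE)
  }
  structure(
    list(
      feature = feature,
      mean = vapply(v, mean, numeric(1)),
      sd = vapply(v, stats::sd, numeric(1)),
      n = lengths(v),
      p_value = mann_whitney(v$melanoma, v$nevus)$p_value,
      fivenum = lapply(v, stats::fivenum)
    ),
    class = "class_summary"
  )
}

#' Full per-classifier evaluation report
#'
#' Bundles the confusion matrix, all metrics and (optionally) the AUC
#' for one classifier, in the layout of a per-model results table:
#' per-class precision/recall/F1/support plus overall accuracy.
#'
#' @param y_true,y_pred label vectors.
#' @param auc optional AUC from [roc_auc()].
#' @param name classifier name.
#' @return object of class `classifier_report`.
#' @export
classifier_report <- function(y_true, y_pred, auc = NA_real_,
                              name = "classifier") {
  cm <- confusion(y_true, y_pred)
  structure(
    list(name = name, confusion = cm, metrics = metrics(cm), auc = auc),
    class = "classifier_report"
  )
}

#' Collapse patch-level predictions to image-level by majority vote
#'
#' Each image is assigned the label predicted for the majority of its
#' patches (ties go to melanoma, the positive class, so a borderline
#' image is flagged rather than cleared).
#'
#' @param image_ids patch-level image id vector.
#' @param y_pred patch-level predicted labels.
#' @param y_true patch-level true labels (constant within an image).
#' @return data.frame with one row per image: `image_id`, `label`,
#'   `pred`.
#' @export
majority_vote <- function(image_ids, y_pred, y_true) {
  stopifnot(length(image_ids) == length(y_pred),
            length(image_ids) == length(y_true))
  yp <- as_class_factor(y_pred)
  yt <- as_class_factor(y_true)
  ids <- unique(image_ids)
  pred <- vapply(ids, function(id) {
    sel <- image_ids == id
    n_mel <- sum(yp[sel] == "melanoma")
    if (n_mel >= sum(sel) / 2) "melanoma" else "nevus"
  }, character(1))
  truth <- vapply(ids, function(id) {
    as.character(yt[image_ids == id][1])
  }, character(1))
  data.frame(image_id = ids, label = truth, pred = pred,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("          predicted\n")
  cat(sprintf("truth      melanoma nevus\n"))
  cat(sprintf("melanoma   %8d %5d\n", x$tp, x$fn))
  cat(sprintf("nevus      %8d %5d\n", x$fp, x$tn))
  invisible(x)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f | sensitivity %.2f | specificity %.2f | fpr %.2f\n",
              x$accuracy, x$sensitivity, x$specificity, x$fpr))
  cat(sprintf("melanoma: precision %.2f recall %.2f F1 %.2f (n=%d)\n",
              x$precision[["melanoma"]], x$recall[["melanoma"]],
              x$f_score[["melanoma"]], x$support[["melanoma"]]))
  cat(sprintf("nevus:    precision %.2f recall %.2f F1 %.2f (n=%d)\n",
              x$precision[["nevus"]], x$recall[["nevus"]],
              x$f_score[["nevus"]], x$support[["nevus"]]))
  invisible(x)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report '%s'%s>\n", x$name,
              if (is.na(x$auc)) "" else sprintf(" AUC=%.4f", x$auc)))
  print(x$metrics)
  invisible(x)
}

#' Write an evaluation report (ranking + per-model metrics) to CSV
#'
#' One row per model and class, mirroring a per-classifier results
#' table: AUC, per-class precision/recall/F1/support, accuracy.
#'
#' @param ranking a `model_ranking` from [rank_by_auc()].
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_report_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "model_ranking"))
  rows <- lapply(ranking$entries$name, function(nm) {
    rep <- ranking$reports[[nm]]
    m <- rep$metrics
    do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
      data.frame(model = nm, auc = rep$auc, class = cl,
                 precision = m$precision[[cl]], recall = m$recall[[cl]],
                 f_score = m$f_score[[cl]], support = m$support[[cl]],
                 accuracy = m$accuracy)
    }))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
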