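# Confusion matrices, per-class metrics, LOPOCV / 70-30 evaluation, and the
# ANOVA + Tukey-Kramer comparison of classifier families.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the fixed order of
#' `classes`.
#'
#' @param y_true,y_pred Equal-length label sequences over known classes.
#' @param classes Class set and order (default `activity_classes()`).
#' @return Integer matrix with class-name dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = activity_classes()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label sequences differ in length")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(y_true, levels = classes),
               factor(y_pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class metrics and overall scores from a confusion matrix
#'
#' For each class, one-vs-rest: precision = TP/(TP+FP), sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), accuracy = (TP+TN)/total, and F1 =
#' the harmonic mean of precision and sensitivity. A zero denominator gives
#' a 0 metric and sets the class's `degenerate` flag. The summary row
#' reports overall accuracy (trace/total) and the macro (unweighted mean)
#' F1; the two are distinct quantities and both are reported.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Object of class `eval_report`: `confusion`, `per_class` data
#'   frame, `overall_accuracy`, `macro_f1`.
#' @export
class_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  rows <- lapply(seq_along(classes), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- total - TP - FN - FP
    precision <- safe_div(TP, TP + FP)
    sensitivity <- safe_div(TP, TP + FN)
    specificity <- safe_div(TN, TN + FP)
    accuracy <- (TP + TN) / total
    f1 <- if (precision + sensitivity == 0) 0 else
      2 * precision * sensitivity / (precision + sensitivity)
    data.frame(class = classes[i], accuracy = accuracy, precision = precision,
               sensitivity = sensitivity, specificity = specificity, f1 = f1,
               degenerate = (TP + FP == 0) || (TP + FN == 0))
  })
  per_class <- do.call(rbind, rows)
  structure(list(confusion = cm, per_class = per_class,
                 overall_accuracy = sum(diag(cm)) / total,
                 macro_f1 = mean(per_class$f1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  overall accuracy: %.4f   macro F1: %.4f\n",
              x$overall_accuracy, x$macro_f1))
  df <- x$per_class
  df[2:6] <- lapply(df[2:6], function(v) sprintf("%.4f", v))
  print(df[1:6], row.names = FALSE)
  invisible(x)
}

#' Stratified 70/30 split of windows
#'
#' Splits window indices into train and test, stratified by activity class
#' so every activity is represented in the stated proportion (within one
#' window per class).
#'
#' @param labels Factor of window labels.
#' @param seed Integer; identical seeds give identical splits.
#' @param train_frac Training fraction (default 0.7).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_70_30 <- function(labels, seed = 1, train_frac = 0.7) {
  labels <- as.factor(labels)
  counts <- table(labels)
  counts <- counts[counts > 0]
  if (any(counts < 4)) {
    stop("class(es) with fewer than 4 windows: ",
         paste(names(counts)[counts < 4], collapse = ", "))
  }
  set.seed(seed)
  train <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(train_frac * length(idx)))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Leave-one-participant-out cross-validation
#'
#' Each participant is held out exactly once; every fitted quantity (gyro
#' scale, class balancing, min-max scaler, optional feature selection, and
#' the classifier) is re-fit from the training fold alone. Test windows are
#' never balanced. Reports the macro F1 per held-out participant and its
#' mean and SD.
#'
#' @param cohort An `imu_cohort` (>= 2 participants).
#' @param kind One of [model_kinds()].
#' @param config An [onset_config()].
#' @param prep Optional precomputed [prepare_windows()] output (reused
#'   across classifier kinds; contains no fold-fitted state).
#' @return Object of class `cv_result`: `fold_f1`, `mean_f1`, `sd_f1`,
#'   per-fold `reports`.
#' @export
lopocv <- function(cohort, kind = "neural_net", config = onset_config(),
                   prep = NULL) {
  if (length(cohort) < 2) stop("LOPOCV needs at least 2 participants")
  if (is.null(prep)) prep <- prepare_windows(cohort, config)
  ids <- unique(prep$participant)
  reports <- vector("list", length(ids))
  f1 <- numeric(length(ids))
  for (i in seq_along(ids)) {
    te <- prep$participant == ids[i]
    fit <- fit_from_windows(prep, which(!te), kind, config)
    pred <- predict_windows(fit, prep, which(te))
    truth <- prep$y[te]
    present <- unique(as.character(truth))
    flagged <- setdiff(activity_classes(), present)
    rep_i <- class_metrics(confusion_matrix(truth, pred$labels))
    if (length(flagged) > 0) {
      # held-out participant lacks some classes: score only present ones
      keep <- rep_i$per_class$class %in% present
      rep_i$macro_f1 <- mean(rep_i$per_class$f1[keep])
      attr(rep_i, "missing_classes") <- flagged
    }
    reports[[i]] <- rep_i
    f1[i] <- rep_i$macro_f1
  }
  names(reports) <- ids
  structure(list(fold_f1 = stats::setNames(f1, ids), mean_f1 = mean(f1),
                 sd_f1 = stats::sd(f1), reports = reports, kind = kind),
            class = "cv_result")
}

#' Compare classifier families by one-way ANOVA and Tukey-Kramer tests
#'
#' Fixed-effects one-way ANOVA on per-fold F1 scores, with studentized-range
#' pairwise comparisons (Tukey-Kramer, valid for unequal group sizes).
#'
#' @param f1_by_classifier Named list of numeric vectors (one per
#'   classifier, each with the per-participant F1 scores).
#' @param alpha Significance level (reported only).
#' @return List: `F`, `df` (c(k-1, N-k)), `p`, `tukey` (data frame of
#'   pairwise differences and adjusted p-values), `alpha`.
#' @export
compare_classifiers <- function(f1_by_classifier, alpha = 0.05) {
  sizes <- lengths(f1_by_classifier)
  if (length(sizes) < 2) stop("need at least 2 classifier groups")
  if (any(sizes < 2)) stop("every group needs at least 2 scores")
  df <- data.frame(
    score = unlist(f1_by_classifier, use.names = FALSE),
    classifier = factor(rep(names(f1_by_classifier), sizes)))
  fit <- stats::aov(score ~ classifier, data = df)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$classifier
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1], tukey = tukey, alpha = alpha)
}
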