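# Confusion matrices, per-class metrics, splits, ANOVA/Tukey machinery.

test_that("confusion matrix counts match brute-force tallies", {
  cm <- confusion_matrix(c("walking", "walking", "sitting"),
                         c("walking", "sitting", "sitting"))
  expect_identical(cm["walking", "walking"], 1L)
  expect_identical(cm["walking", "sitting"], 1L)
  expect_identical(cm["sitting", "sitting"], 1L)
  expect_identical(sum(cm), 3L)
  expect_error(confusion_matrix("walking", "jogging"), "unknown class")
  expect_error(confusion_matrix(c("walking", "sitting"), "walking"), "length")

  set.seed(5)
  classes <- activity_classes()
  y1 <- sample(classes, 1000, replace = TRUE)
  y2 <- sample(classes, 1000, replace = TRUE)
  cm <- confusion_matrix(y1, y2)
  for (cl in classes) {
    expect_identical(sum(cm[cl, ]), sum(y1 == cl))
    expect_identical(sum(cm[, cl]), sum(y2 == cl))
    for (cl2 in classes) {
      expect_identical(cm[cl, cl2], sum(y1 == cl & y2 == cl2))
    }
  }
})

test_that("per-class metrics agree with independent tallies", {
  classes <- activity_classes()
  # diagonal matrix: everything perfect
  cm <- diag(5L, 8)
  dimnames(cm) <- list(true = classes, predicted = classes)
  rep <- class_metrics(cm)
  expect_true(all(abs(as.matrix(rep$per_class[2:6]) - 1) == 0))
  expect_identical(rep$overall_accuracy, 1)
  expect_identical(rep$macro_f1, 1)

  # hand-computed binary example
  cmb <- matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE,
                dimnames = list(true = classes[1:2], predicted = classes[1:2]))
  repb <- class_metrics(cmb)
  expect_equal(repb$per_class$precision[1], 8 / 9)
  expect_equal(repb$per_class$sensitivity[1], 0.8)
  expect_equal(repb$per_class$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))

  # degenerate class: no true or predicted windows -> flagged zeros
  cmd <- diag(c(0L, 5L, 5L, 5L, 5L, 5L, 5L, 5L))
  dimnames(cmd) <- list(true = classes, predicted = classes)
  repd <- class_metrics(cmd)
  expect_identical(repd$per_class$precision[1], 0)
  expect_true(repd$per_class$degenerate[1])

  # property: 1000 random confusion instances vs brute-force label tallies
  set.seed(11)
  for (i in 1:40) {
    n <- sample(50:200, 1)
    y1 <- sample(classes, n, replace = TRUE)
    y2 <- sample(classes, n, replace = TRUE)
    rep <- class_metrics(confusion_matrix(y1, y2))
    ref <- brute_metrics(y1, y2, classes)
    got <- t(as.matrix(rep$per_class[c("accuracy", "precision", "sensitivity",
                                       "specificity", "f1")]))
    dimnames(got) <- dimnames(ref)
    expect_equal(got, ref, tolerance = 1e-12)
    expect_equal(rep$overall_accuracy, mean(y1 == y2), tolerance = 1e-12)
  }
})

test_that("stratified 70/30 split is proportional and deterministic", {
  set.seed(2)
  labels <- factor(sample(activity_classes(), 800, replace = TRUE),
                   levels = activity_classes())
  sp <- split_70_30(labels, seed = 6)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  for (cl in activity_classes()) {
    frac <- sum(labels[sp$train] == cl) / sum(labels == cl)
    expect_true(abs(frac - 0.7) < 0.71 - 0.69 + 1 / sum(labels == cl))
  }
  expect_identical(sp, split_70_30(labels, seed = 6))
  expect_error(split_70_30(factor(c("sitting", "sitting", "sitting"),
                                  levels = activity_classes())),
               "fewer than 4")
})

test_that("one-way ANOVA df and Tukey-Kramer comparisons are correct", {
  # 5 groups x 20 -> df (4, 95)
  set.seed(3)
  groups <- lapply(1:5, function(i) rnorm(20, mean = 0.8))
  names(groups) <- paste0("m", 1:5)
  res <- compare_classifiers(groups)
  expect_identical(res$df, c(4L, 95L))
  expect_identical(nrow(res$tukey), 10L)

  # hand-checkable 3-group ANOVA (textbook-style computation)
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res3 <- compare_classifiers(g)
  gm <- mean(unlist(g))
  ssb <- 3 * sum((sapply(g, mean) - gm)^2)
  ssw <- sum(sapply(g, function(v) sum((v - mean(v))^2)))
  F_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res3$F, F_hand, tolerance = 1e-10)

  # overwhelming separation
  g2 <- list(a = rnorm(20, 0, 0.1), b = rnorm(20, 5, 0.1))
  expect_lt(compare_classifiers(g2)$p, 1e-6)

  expect_error(compare_classifiers(list(a = 1, b = c(1, 2))), "at least 2 scores")
  expect_error(compare_classifiers(list(a = c(1, 2))), "2 classifier groups")
})

test_that("ANOVA type-I error rate is nominal under the null", {
  set.seed(17)
  reps <- 400
  rejections <- 0L
  for (i in seq_len(reps)) {
    groups <- lapply(1:5, function(j) rnorm(20))
    names(groups) <- paste0("g", 1:5)
    if (compare_classifiers(groups)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / reps, 0.02)
  expect_lt(rejections / reps, 0.08)
})
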