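# The five classifier families: shared contract, determinism, the neural
# network's architecture invariants and SCG trainer.

toy_blobs <- function(n = 60, seed = 1, sd = 0.2) {
  set.seed(seed)
  y <- factor(rep(c("sitting", "walking", "turning"), each = n),
              levels = activity_classes())
  mu <- rbind(c(0, 0), c(2, 0), c(0, 2))
  X <- mu[rep(1:3, each = n), ] + matrix(rnorm(6 * n, 0, sd), 3 * n, 2)
  colnames(X) <- c("f1", "f2")
  list(X = X, y = droplevels(y))
}

test_that("all five kinds share the train/predict contract and are seeded", {
  d <- toy_blobs()
  probe <- toy_blobs(seed = 99)$X
  for (kind in model_kinds()) {
    m1 <- train_model(kind, d$X, d$y, seed = 4)
    m2 <- train_model(kind, d$X, d$y, seed = 4)
    p1 <- predict(m1, probe)
    p2 <- predict(m2, probe)
    expect_identical(p1$labels, p2$labels, info = kind)
    expect_identical(dim(p1$scores), c(nrow(probe), nlevels(d$y)), info = kind)
    # separable blobs: essentially perfect training accuracy
    acc <- mean(predict(m1, d$X)$labels == d$y)
    expect_gte(acc, 0.98)
    # empty input -> empty output
    p0 <- predict(m1, d$X[0, , drop = FALSE])
    expect_length(p0$labels, 0)
  }
  expect_error(train_model("linear_svm", d$X, factor(rep("sitting", nrow(d$X)))),
               "single class")
})

test_that("feature mismatch is reported with the offending columns", {
  d <- toy_blobs()
  m <- train_model("linear_svm", d$X, d$y)
  bad <- d$X; colnames(bad) <- c("f1", "weird")
  expect_error(predict(m, bad), "weird")
  # reordered columns are accepted and realigned
  p_re <- predict(m, d$X[, c("f2", "f1")])
  expect_identical(p_re$labels, predict(m, d$X)$labels)
})

test_that("the neural network solves XOR and keeps its activation invariants", {
  set.seed(2)
  n <- 400
  X <- matrix(runif(2 * n), n, 2)
  y <- factor(ifelse(xor(X[, 1] > 0.5, X[, 2] > 0.5), "walking", "sitting"))
  colnames(X) <- c("f1", "f2")
  m <- train_model("neural_net", X, y,
                   hyper = list(nn = nn_spec(25, max_iter = 800)), seed = 1)
  expect_gte(mean(predict(m, X)$labels == y), 0.99)
  # hidden softmax rows sum to 1; tanh outputs within (-1, 1)
  fwd <- gaitonset:::nn_forward(m$fit$par, X, "competitive")
  expect_equal(rowSums(fwd$H), rep(1, n), tolerance = 1e-12)
  expect_true(all(abs(fwd$Y) <= 1))
  # scores equal the tanh outputs
  expect_equal(unname(predict(m, X)$scores), unname(fwd$Y))
})

test_that("SCG decreases the best-so-far training loss monotonically", {
  d <- toy_blobs(n = 80, sd = 0.5)
  m <- train_model("neural_net", d$X, d$y,
                   hyper = list(nn = nn_spec(10, max_iter = 200)), seed = 3)
  tr <- m$fit$loss_trace
  expect_gt(length(tr), 5)
  best <- cummin(tr)
  expect_true(all(diff(best) <= 1e-12))
})

test_that("the conventional variant trains too and differs from competitive", {
  d <- toy_blobs()
  mc <- train_model("neural_net", d$X, d$y,
                    hyper = list(nn = nn_spec(10, max_iter = 200,
                                              variant = "conventional")),
                    seed = 5)
  expect_gte(mean(predict(mc, d$X)$labels == d$y), 0.98)
  fwd <- gaitonset:::nn_forward(mc$fit$par, d$X, "conventional")
  expect_equal(rowSums(fwd$Y), rep(1, nrow(d$X)), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(6)
  p <- 3; h <- 4; k <- 2; n <- 12
  X <- matrix(rnorm(n * p), n, p)
  Tgt <- matrix(sample(c(-1, 1), n * k, replace = TRUE), n, k)
  for (variant in c("competitive", "conventional")) {
    w <- rnorm(p * h + h + h * k + k, 0, 0.5)
    lg <- gaitonset:::nn_loss_grad(w, X, Tgt, p, h, k, variant, decay = 1e-3)
    num <- vapply(seq_along(w), function(i) {
      e <- rep(0, length(w)); e[i] <- 1e-6
      (gaitonset:::nn_loss_grad(w + e, X, Tgt, p, h, k, variant, 1e-3)$loss -
         gaitonset:::nn_loss_grad(w - e, X, Tgt, p, h, k, variant, 1e-3)$loss) / 2e-6
    }, numeric(1))
    expect_equal(lg$grad, num, tolerance = 1e-5)
  }
})

test_that("models round-trip through serialization with identical predictions", {
  d <- toy_blobs()
  probe <- toy_blobs(seed = 123)$X
  for (kind in c("neural_net", "decision_tree", "linear_svm")) {
    m <- train_model(kind, d$X, d$y, seed = 2)
    f <- withr::local_tempfile(fileext = ".rds")
    saveRDS(m, f)
    m2 <- readRDS(f)
    expect_identical(predict(m2, probe)$labels, predict(m, probe)$labels)
  }
})

test_that("hidden-layer grid search is exhaustive and honours a singleton grid", {
  coh <- small_cohort(3, 0, seed = 7)
  cfg <- fast_config()
  res <- grid_search_hidden(coh, n_range = 25, window_grid = 100,
                            overlap_grid = 0.9, config = cfg, n_folds = 2)
  expect_identical(nrow(res$table), 1L)
  expect_identical(res$best$n_hidden, 25)
  res2 <- grid_search_hidden(coh, n_range = c(15, 25), window_grid = c(100, 200),
                             overlap_grid = 0.9, config = fast_config(), n_folds = 2)
  expect_identical(nrow(res2$table), 4L)
  expect_true(all(!is.na(res2$table$score)))
  expect_identical(res2$best$score, max(res2$table$score))
})
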