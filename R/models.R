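# The five classifier families behind one train/predict contract.
# The neural network (single hidden layer, soft-competitive hidden
# activation, symmetric-sigmoid output, scaled-conjugate-gradient trainer)
# is authored here; decision tree, KNN, linear SVM and logistic regression
# wrap the standard implementations.

#' Names of the five classifier families
#' @return Character vector.
#' @export
model_kinds <- function() {
  c("decision_tree", "knn", "linear_svm", "linear_logistic", "neural_net")
}

#' Neural-network specification
#'
#' A single hidden layer. The default activations mirror the recognition
#' model as specified: a soft competitive transfer (softmax) on the hidden
#' layer and a symmetric sigmoid (tanh) on the 8 output units, trained by
#' full-batch scaled conjugate gradients on one-hot targets in \{-1, +1\}
#' with argmax decoding. `variant = "conventional"` swaps to the usual
#' tanh-hidden / softmax-output ordering.
#'
#' @param n_hidden Hidden units (grid-search range 15-27; default 25).
#' @param max_iter SCG iteration cap.
#' @param tol Stop when the gradient norm falls below this.
#' @param variant `"competitive"` (softmax hidden, tanh output; default) or
#'   `"conventional"` (tanh hidden, softmax output).
#' @param weight_decay L2 penalty on the weights (biases free); a small
#'   default keeps held-out participants' postures from being carved away
#'   by participant-specific boundaries.
#' @return Object of class `nn_spec`.
#' @export
nn_spec <- function(n_hidden = 25, max_iter = 300, tol = 1e-6,
                    variant = c("competitive", "conventional"),
                    weight_decay = 1e-4) {
  variant <- match.arg(variant)
  stopifnot(n_hidden >= 1, weight_decay >= 0)
  structure(list(n_hidden = n_hidden, max_iter = max_iter, tol = tol,
                 variant = variant, weight_decay = weight_decay),
            class = "nn_spec")
}

# row-wise softmax
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# deterministic matrix product via per-column rowSums: row i of the result
# depends only on row i of X and is computed identically whether X has one
# row or many (streaming/offline bit-equality).
mat_mult_det <- function(X, W) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(W))
  for (j in seq_len(ncol(W))) {
    out[, j] <- rowSums(X * rep(W[, j], each = n))
  }
  out
}

nn_forward <- function(par, X, variant) {
  Z1 <- mat_mult_det(X, par$W1) + rep(par$b1, each = nrow(X))
  if (variant == "competitive") {
    H <- softmax_rows(Z1)
    Z2 <- mat_mult_det(H, par$W2) + rep(par$b2, each = nrow(X))
    Y <- tanh(Z2)
  } else {
    H <- tanh(Z1)
    Z2 <- mat_mult_det(H, par$W2) + rep(par$b2, each = nrow(X))
    Y <- softmax_rows(Z2)
  }
  list(H = H, Y = Y)
}

# flat parameter vector <-> weight list
nn_unflatten <- function(w, p, h, k) {
  i <- 0
  W1 <- matrix(w[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- w[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# loss (half mean squared error over all outputs) and gradient, full batch
nn_loss_grad <- function(w, X, Tgt, p, h, k, variant, decay = 0) {
  n <- nrow(X)
  par <- nn_unflatten(w, p, h, k)
  Z1 <- X %*% par$W1 + rep(par$b1, each = n)
  if (variant == "competitive") {
    H <- softmax_rows(Z1)
    Z2 <- H %*% par$W2 + rep(par$b2, each = n)
    Y <- tanh(Z2)
    R <- Y - Tgt
    loss <- 0.5 * sum(R * R) / n
    dZ2 <- R * (1 - Y * Y) / n
    dH <- dZ2 %*% t(par$W2)
    dZ1 <- H * (dH - rowSums(dH * H))
  } else {
    H <- tanh(Z1)
    Z2 <- H %*% par$W2 + rep(par$b2, each = n)
    Y <- softmax_rows(Z2)
    R <- Y - Tgt
    loss <- 0.5 * sum(R * R) / n
    dZ2 <- (R * Y - Y * rowSums(R * Y)) / n
    dH <- dZ2 %*% t(par$W2)
    dZ1 <- (1 - H * H) * dH
  }
  g <- c(crossprod(X, dZ1), colSums(dZ1), crossprod(H, dZ2), colSums(dZ2))
  if (decay > 0) {
    # L2 penalty on weights only (biases free): smooths decision boundaries
    mask <- rep(c(1, 0, 1, 0), c(p * h, h, h * k, k))
    loss <- loss + 0.5 * decay * sum((w * mask)^2)
    g <- g + decay * w * mask
  }
  list(loss = loss, grad = g)
}

# Scaled conjugate gradient (Moller 1993): Hessian-free conjugate directions
# with adaptive scale regularization; full batch, deterministic.
scg_optim <- function(w, fn_loss_grad, max_iter = 300, tol = 1e-6) {
  sigma0 <- 1e-4
  lambda <- 1e-6; lambda_bar <- 0
  lg <- fn_loss_grad(w)
  f <- lg$loss
  r <- -lg$grad
  p <- r
  success <- TRUE
  loss_trace <- numeric(max_iter)
  N <- length(w)
  delta <- 0
  for (k in seq_len(max_iter)) {
    p2 <- sum(p * p)
    if (p2 < .Machine$double.eps) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g2 <- fn_loss_grad(w + sigma * p)$grad
      s <- (g2 - (-r)) / sigma          # -r is the current gradient
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    lg_new <- fn_loss_grad(w + alpha * p)
    Delta <- 2 * delta_k * (f - lg_new$loss) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      f_old <- f
      f <- lg_new$loss
      r_new <- -lg_new$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% N == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- 0.25 * lambda
      if (sqrt(sum(r * r)) < tol || abs(f_old - f) < tol * 1e-3) {
        loss_trace[k] <- f
        loss_trace <- loss_trace[seq_len(k)]
        break
      }
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (lambda > 1e100) break
    loss_trace[k] <- f
    if (k == max_iter) loss_trace <- loss_trace[seq_len(k)]
  }
  list(w = w, loss = f, trace = loss_trace[loss_trace != 0 | seq_along(loss_trace) == 1])
}

nn_train <- function(X, y, spec = nn_spec(), seed = 1) {
  classes <- levels(y)
  k <- length(classes)
  p <- ncol(X)
  h <- spec$n_hidden
  Tgt <- outer(as.integer(y), seq_len(k), function(a, b) ifelse(a == b, 1, -1))
  set.seed(seed)
  if (spec$variant == "competitive" && nrow(X) >= h) {
    # competitive init: hidden units as prototypes drawn from the training
    # rows so that softmax(Z1) responds to (negative squared) distance from
    # each prototype; output layer initialised by ridge regression onto the
    # pre-squashed targets. SCG then refines all weights jointly.
    beta <- 1
    # prototypes are bootstrap class centroids (classes cycled so every
    # class seeds at least one hidden unit): averaging within a class
    # cancels participant-specific posture offsets, which random training
    # rows would bake into the units
    per_cl <- split(seq_len(nrow(X)), y)
    proto <- t(vapply(seq_len(h), function(j) {
      ix <- per_cl[[(j - 1L) %% k + 1L]]
      colMeans(X[sample(ix, length(ix), replace = TRUE), , drop = FALSE])
    }, numeric(p)))
    W1 <- beta * t(proto)
    b1 <- -beta * rowSums(proto * proto) / 2
    H <- softmax_rows(X %*% W1 + rep(b1, each = nrow(X)))
    Ha <- cbind(H, 1)
    Wr <- solve(crossprod(Ha) + diag(1e-3, h + 1),
                crossprod(Ha, atanh(0.95 * Tgt)))
    w0 <- c(W1, b1, Wr[seq_len(h), ], Wr[h + 1, ])
  } else {
    w0 <- stats::runif(p * h + h + h * k + k, -0.5, 0.5) / sqrt(p)
  }
  decay <- if (is.null(spec$weight_decay)) 0 else spec$weight_decay
  fit <- scg_optim(w0,
                   function(w) nn_loss_grad(w, X, Tgt, p, h, k, spec$variant,
                                            decay),
                   max_iter = spec$max_iter, tol = spec$tol)
  list(par = nn_unflatten(fit$w, p, h, k), spec = spec, classes = classes,
       loss = fit$loss, loss_trace = fit$trace)
}

#' Train a classifier
#'
#' All five kinds expose the same contract: fit on a scaled,
#' feature-selected, class-balanced training matrix; predict labels plus
#' per-class scores. Hyperparameters follow the recognition design: KNN uses
#' 3 neighbours; SVM and logistic regression are linear with one-vs-rest
#' wrapping; the decision tree splits on Gini with no depth cap; the neural
#' network follows its [nn_spec()].
#'
#' @param kind One of [model_kinds()].
#' @param X Numeric feature matrix (named columns).
#' @param y Labels (factor or character).
#' @param hyper Optional list: `k` (KNN), `cost` (SVM), `nn` (an [nn_spec()]).
#' @param seed Integer; results are deterministic given the seed.
#' @return Object of class `activity_classifier`.
#' @export
train_model <- function(kind, X, y, hyper = list(), seed = 1) {
  kind <- match.arg(kind, model_kinds())
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  stopifnot(nrow(X) == length(y))
  classes <- levels(y)
  fit <- switch(kind,
    decision_tree = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(cp = 1e-3, xval = 0,
                                                  maxdepth = 30))
    },
    knn = list(train = X, cl = y, k = if (is.null(hyper$k)) 3L else hyper$k),
    linear_svm = {
      cost <- if (is.null(hyper$cost)) 1 else hyper$cost
      lapply(classes, function(cl) {
        e1071::svm(X, factor(ifelse(y == cl, "pos", "neg"),
                             levels = c("pos", "neg")),
                   kernel = "linear", cost = cost, scale = FALSE)
      })
    },
    linear_logistic = {
      Xi <- cbind(1, X)
      W <- vapply(classes, function(cl) {
        co <- suppressWarnings(
          stats::glm.fit(Xi, as.numeric(y == cl),
                         family = stats::binomial(),
                         control = list(maxit = 50)))$coefficients
        co[is.na(co)] <- 0
        co
      }, numeric(ncol(Xi)))
      W
    },
    neural_net = {
      spec <- if (is.null(hyper$nn)) nn_spec() else hyper$nn
      nn_train(X, y, spec, seed)
    })
  structure(list(kind = kind, fit = fit, classes = classes,
                 features = colnames(X), seed = seed),
            class = "activity_classifier")
}

#' Predict activity labels and scores
#'
#' @param object An `activity_classifier`.
#' @param X Feature matrix whose columns match the training features.
#' @param ... Unused.
#' @return List with `labels` (factor over the training classes) and
#'   `scores` (matrix, one column per class; larger means more confident).
#' @export
predict.activity_classifier <- function(object, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0) {
    return(list(labels = factor(character(0), levels = object$classes),
                scores = matrix(0, 0, length(object$classes))))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), object$features)) {
    missing <- setdiff(object$features, colnames(X))
    extra <- setdiff(colnames(X), object$features)
    if (length(missing) || length(extra)) {
      stop("feature mismatch; missing: [", paste(missing, collapse = ", "),
           "] extra: [", paste(extra, collapse = ", "), "]")
    }
    X <- X[, object$features, drop = FALSE]
  }
  classes <- object$classes
  scores <- switch(object$kind,
    decision_tree = {
      df <- as.data.frame(X)
      stats::predict(object$fit, df, type = "prob")[, classes, drop = FALSE]
    },
    knn = {
      set.seed(object$seed)
      pr <- class::knn(object$fit$train, X, object$fit$cl, k = object$fit$k,
                       prob = TRUE)
      s <- matrix(0, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
      s[cbind(seq_len(nrow(X)), match(as.character(pr), classes))] <-
        attr(pr, "prob")
      s
    },
    linear_svm = {
      s <- vapply(object$fit, function(f) {
        dv <- attr(stats::predict(f, X, decision.values = TRUE),
                   "decision.values")
        drop(dv) * if (colnames(dv) == "pos/neg") 1 else -1
      }, numeric(nrow(X)))
      matrix(s, nrow(X), dimnames = list(NULL, classes))
    },
    linear_logistic = {
      s <- cbind(1, X) %*% object$fit
      colnames(s) <- classes
      s
    },
    neural_net = {
      s <- nn_forward(object$fit$par, X, object$fit$spec$variant)$Y
      colnames(s) <- classes
      s
    })
  idx <- max.col(scores, ties.method = "first")
  list(labels = factor(classes[idx], levels = classes), scores = scores)
}

#' Grid search over hidden-layer size and window configuration
#'
#' Exhaustively trains the neural network for every combination of hidden
#' units, window length and overlap, scoring each by participant-grouped
#' cross-validated accuracy, and returns the argmax with the full score
#' table.
#'
#' @param cohort An `imu_cohort`.
#' @param n_range Hidden-unit candidates (e.g. 15:27).
#' @param window_grid Window lengths in ms.
#' @param overlap_grid Overlap fractions.
#' @param config Pipeline configuration ([onset_config()]).
#' @param n_folds Grouped CV folds.
#' @return List with `best` (row of the table) and `table` (all scores).
#' @export
grid_search_hidden <- function(cohort, n_range = 15:27, window_grid = 100,
                               overlap_grid = 0.9, config = onset_config(),
                               n_folds = 3) {
  grid <- expand.grid(n_hidden = n_range, window_ms = window_grid,
                      overlap = overlap_grid)
  grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$window <- window_spec(grid$window_ms[i], grid$overlap[i])
    cfg$nn <- nn_spec(grid$n_hidden[i], max_iter = cfg$nn$max_iter,
                      variant = cfg$nn$variant)
    prep <- prepare_windows(cohort, cfg)
    folds <- grouped_folds(prep$participant, n_folds, seed = cfg$seed)
    acc <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      fit <- fit_from_windows(prep, which(tr), "neural_net", cfg)
      pred <- predict(fit$model,
                      apply_scaler(prep$X[!tr, fit$features, drop = FALSE],
                                   fit$scaler))
      mean(pred$labels == prep$y[!tr])
    }, numeric(1))
    grid$score[i] <- mean(acc)
  }
  list(best = grid[which.max(grid$score), ], table = grid)
}
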