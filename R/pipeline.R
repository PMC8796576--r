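# End-to-end pipeline plumbing: configuration, window preparation, and
# fitting/applying a complete recognition bundle.

#' Pipeline configuration
#'
#' @param window A [window_spec()].
#' @param fusion_gain Orientation-filter tilt-correction weight.
#' @param calibration_window Seconds `c(t0, t1)` of the initial static
#'   segment used for bias estimation.
#' @param balance Balance training classes by down-sampling (default TRUE).
#' @param n_per_class Optional cap on training windows per class after
#'   balancing (a problem-size control; `NULL` keeps the minimum class
#'   count).
#' @param feature_selection `"none"` (use the full catalogue) or `"rfe"`
#'   (SVM-based recursive feature elimination inside the training data).
#' @param rfe_sizes Candidate subset sizes for RFE (default all).
#' @param catalogue Feature catalogue data frame.
#' @param nn An [nn_spec()] for the neural network.
#' @param knn_k Neighbours for KNN.
#' @param svm_cost Cost for the linear SVM.
#' @param seed Master seed for balancing, folds and model training.
#' @return Object of class `onset_config`.
#' @export
onset_config <- function(window = window_spec(), fusion_gain = 0.02,
                         calibration_window = c(0, 2), balance = TRUE,
                         n_per_class = NULL,
                         feature_selection = c("none", "rfe"),
                         rfe_sizes = NULL, catalogue = feature_catalogue(),
                         nn = nn_spec(), knn_k = 3, svm_cost = 1, seed = 1) {
  feature_selection <- match.arg(feature_selection)
  structure(list(window = window, fusion_gain = fusion_gain,
                 calibration_window = calibration_window, balance = balance,
                 n_per_class = n_per_class,
                 feature_selection = feature_selection, rfe_sizes = rfe_sizes,
                 catalogue = catalogue, nn = nn, knn_k = knn_k,
                 svm_cost = svm_cost, seed = as.integer(seed)),
            class = "onset_config")
}

# Gyro-derived feature columns scale linearly with the channel scale
# (mean, sd, min, max and slope are all homogeneous of degree one), so
# features can be extracted once from unscaled rates and rescaled per
# training fold without leaking test data into the scale fit.
scale_features <- function(X, catalogue, gyro_scale) {
  gsel <- catalogue$channel %in% names(gyro_scale)
  if (any(gsel)) {
    div <- gyro_scale[catalogue$channel[gsel]]
    X[, gsel] <- X[, gsel, drop = FALSE] / rep(div, each = nrow(X))
  }
  X
}

#' Preprocess a set of participants into windowed features
#'
#' Runs the fold-independent stages once per participant: bias estimation
#' from the initial static window, orientation fusion, sliding-window
#' segmentation with majority-vote labels, and feature extraction (with
#' unscaled angular rates; per-fold gyro scaling is applied to the feature
#' matrix afterwards, see [fit_from_windows()]).
#'
#' @param participants An `imu_cohort` (list of `list(log, labels, profile)`).
#' @param config An [onset_config()].
#' @return List: feature matrix `X`, window labels `y`, `participant` id per
#'   window, per-participant `max_abs_gyro` (for fold-wise scale fitting)
#'   and `preprocess` params.
#' @export
prepare_windows <- function(participants, config = onset_config()) {
  spec <- config$window
  parts <- lapply(participants, function(p) {
    pp <- estimate_bias(p$log, config$calibration_window)
    logc <- apply_bias(p$log, pp)
    quats <- fuse_log(logc, config$fusion_gain, spec$fs)
    channels <- build_channel_matrix(logc, quats)
    starts <- make_windows(nrow(logc), spec)
    y <- window_labels(sample_labels(p$log, p$labels), starts, spec)
    X <- extract_features(channels, starts, spec, config$catalogue)
    mg <- vapply(gyro_channels(), function(ch) max(abs(logc[[ch]])), numeric(1))
    id <- p$profile$participant_id
    list(X = X, y = y, id = rep(id, length(starts)), max_abs_gyro = mg,
         preprocess = pp,
         t = p$log$t[starts + spec$samples_per_window - 1L])
  })
  ids <- vapply(parts, function(p) p$id[1], character(1))
  names(parts) <- ids
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = factor(unlist(lapply(parts, function(p) as.character(p$y))),
                  levels = activity_classes()),
       participant = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
       t = unlist(lapply(parts, `[[`, "t"), use.names = FALSE),
       max_abs_gyro = do.call(rbind, lapply(parts, `[[`, "max_abs_gyro")),
       preprocess = lapply(parts, `[[`, "preprocess"),
       catalogue = config$catalogue)
}

#' Fit scaling, selection and a classifier on a subset of prepared windows
#'
#' The training-only stages: gyro-scale fitting (from the training
#' participants' maxima), class balancing, min-max scaler fitting, optional
#' RFE, and model training. Nothing outside `rows` influences any fitted
#' parameter.
#'
#' @param prep Output of [prepare_windows()].
#' @param rows Integer indices of the training windows.
#' @param kind One of [model_kinds()].
#' @param config An [onset_config()].
#' @return List: `model`, `scaler`, `features`, `selection`, `gyro_scale`.
#' @export
fit_from_windows <- function(prep, rows, kind, config = onset_config()) {
  train_ids <- unique(prep$participant[rows])
  gyro_scale <- apply(prep$max_abs_gyro[train_ids, , drop = FALSE], 2, max)
  zero <- gyro_scale == 0
  if (any(zero)) {
    warning("all-zero gyro channel(s) in training data; scale set to 1")
    gyro_scale[zero] <- 1
  }
  X <- scale_features(prep$X[rows, , drop = FALSE], prep$catalogue, gyro_scale)
  y <- prep$y[rows]
  if (isTRUE(config$balance)) {
    keep <- balance_classes(y, seed = config$seed,
                            n_per_class = config$n_per_class)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    groups <- prep$participant[rows][keep]
  } else {
    groups <- prep$participant[rows]
  }
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  selection <- NULL
  features <- colnames(Xs)
  if (config$feature_selection == "rfe") {
    selection <- rfe_select(Xs, y, groups, sizes = config$rfe_sizes,
                            cost = config$svm_cost, seed = config$seed)
    features <- selection$chosen
  }
  hyper <- list(k = config$knn_k, cost = config$svm_cost, nn = config$nn)
  model <- train_model(kind, Xs[, features, drop = FALSE], y, hyper,
                       seed = config$seed)
  list(model = model, scaler = scaler, features = features,
       selection = selection, gyro_scale = gyro_scale)
}

# predict prepared windows with a fitted fold model
predict_windows <- function(fit, prep, rows) {
  X <- scale_features(prep$X[rows, , drop = FALSE], prep$catalogue,
                      fit$gyro_scale)
  Xs <- apply_scaler(X, fit$scaler)[, fit$features, drop = FALSE]
  predict(fit$model, Xs)
}

#' Train a complete recognition bundle
#'
#' Fits every stage on the given participants and packages the result so
#' that offline batch classification and the streaming engine can reproduce
#' each other exactly: the bundle carries the classifier together with its
#' gyro scale, min-max scaler, selected features, feature catalogue, window
#' spec and fusion settings.
#'
#' @param participants An `imu_cohort`.
#' @param kind One of [model_kinds()] (default the neural network).
#' @param config An [onset_config()].
#' @return Object of class `onset_model`.
#' @export
fit_onset_model <- function(participants, kind = "neural_net",
                            config = onset_config()) {
  prep <- prepare_windows(participants, config)
  fit <- fit_from_windows(prep, seq_along(prep$y), kind, config)
  structure(list(kind = kind, model = fit$model, scaler = fit$scaler,
                 features = fit$features, selection = fit$selection,
                 gyro_scale = fit$gyro_scale, catalogue = config$catalogue,
                 window = config$window, fusion_gain = config$fusion_gain,
                 calibration_window = config$calibration_window,
                 classes = fit$model$classes, config = config),
            class = "onset_model")
}

#' Offline (batch) classification of a signal log
#'
#' Replays the training-time path on a full recording: bias correction,
#' orientation fusion, gyro scaling with the stored training scale, window
#' segmentation, feature extraction, min-max scaling, selection, and batch
#' prediction. One prediction per window, stamped with the window's last
#' sample time.
#'
#' @param bundle An `onset_model`.
#' @param log A `signal_log`.
#' @param preprocess Optional precomputed `preprocess_params` (shared with a
#'   streaming run for like-for-like comparison); estimated from the log's
#'   calibration window when `NULL`.
#' @return Data frame: `t`, `label`, and one `score_*` column per class.
#' @export
offline_predict <- function(bundle, log, preprocess = NULL) {
  spec <- bundle$window
  if (is.null(preprocess)) preprocess <- estimate_bias(log, bundle$calibration_window)
  logc <- apply_bias(log, preprocess)
  quats <- fuse_log(logc, bundle$fusion_gain, spec$fs)
  logs <- apply_gyro_scale(logc, bundle$gyro_scale)
  channels <- build_channel_matrix(logs, quats)
  starts <- make_windows(nrow(log), spec)
  X <- extract_features(channels, starts, spec, bundle$catalogue)
  Xs <- apply_scaler(X, bundle$scaler)[, bundle$features, drop = FALSE]
  pred <- predict(bundle$model, Xs)
  out <- data.frame(t = log$t[starts + spec$samples_per_window - 1L],
                    label = pred$labels)
  sc <- as.data.frame(pred$scores)
  names(sc) <- paste0("score_", bundle$classes)
  cbind(out, sc)
}

#' Evaluate a bundle on one labelled recording
#'
#' @param bundle An `onset_model`.
#' @param log A `signal_log`.
#' @param labels The matching `label_track`.
#' @return An `eval_report` (see [class_metrics()]), with the per-window
#'   predictions attached as attribute `predictions`.
#' @export
evaluate_model <- function(bundle, log, labels) {
  spec <- bundle$window
  preds <- offline_predict(bundle, log)
  starts <- make_windows(nrow(log), spec)
  truth <- window_labels(sample_labels(log, labels), starts, spec)
  rep <- class_metrics(confusion_matrix(truth, preds$label))
  attr(rep, "predictions") <- preds
  rep
}
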