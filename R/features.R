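# Windowed time-domain features, min-max scaling, and SVM-based recursive
# feature elimination.

#' The 55-entry time-domain feature catalogue
#'
#' Each entry pairs a per-sample channel (a scaled gyro axis, an
#' accelerometer axis, a quaternion-derived pitch/roll angle, or a derived
#' signal-magnitude-area trace) with a window statistic. The default
#' catalogue is:
#' \itemize{
#'   \item 9 scaled gyro channels x \{mean, sd, slope\} (27),
#'   \item 9 accelerometer channels x \{mean, sd\} (18),
#'   \item per-sensor accelerometer signal-magnitude area, mean (3),
#'   \item per-sensor pitch mean and roll mean from the orientation
#'     estimate (6),
#'   \item sternum pitch slope (1).
#' }
#' `slope` is the least-squares linear-fit slope per sample step. The
#' catalogue is a plain data frame, so an alternative list (statistics
#' `mean`, `sd`, `min`, `max`, `slope` over any available channel) can be
#' swapped in via the `catalogue` arguments downstream.
#'
#' @return Data frame with columns `name`, `channel`, `stat` (55 rows).
#' @export
feature_catalogue <- function() {
  g <- gyro_channels(); a <- accel_channels()
  rows <- rbind(
    expand.grid(channel = g, stat = c("mean", "sd", "slope"),
                stringsAsFactors = FALSE),
    expand.grid(channel = a, stat = c("mean", "sd"),
                stringsAsFactors = FALSE),
    data.frame(channel = paste0("sma_", c("s1", "s2", "s3")), stat = "mean"),
    data.frame(channel = paste0("pitch_", c("s1", "s2", "s3")), stat = "mean"),
    data.frame(channel = paste0("roll_", c("s1", "s2", "s3")), stat = "mean"),
    data.frame(channel = "pitch_s1", stat = "slope"))
  rows$name <- paste(rows$channel, rows$stat, sep = "_")
  rows[c("name", "channel", "stat")]
}

#' Per-sample channel matrix for feature extraction
#'
#' Binds the 18 (scaled) raw channels with the derived per-sample traces the
#' catalogue can reference: per-sensor accelerometer signal-magnitude area
#' (`|ax| + |ay| + |az|`) and pitch/roll (degrees) from the orientation
#' estimate.
#'
#' @param log A bias-corrected, gyro-scaled `signal_log`.
#' @param quats Per-sensor quaternion list from [fuse_log()].
#' @return Numeric matrix `n x 27` with named columns.
#' @export
build_channel_matrix <- function(log, quats) {
  raw <- as.matrix(log[signal_channels()])
  extra <- lapply(names(sensor_names()), function(s) {
    acc <- raw[, paste0(s, "_", c("ax", "ay", "az")), drop = FALSE]
    ang <- orientation_angles(quats[[s]])
    m <- cbind(abs(acc[, 1]) + abs(acc[, 2]) + abs(acc[, 3]),
               ang[, "pitch"], ang[, "roll"])
    colnames(m) <- paste0(c("sma_", "pitch_", "roll_"), s)
    m
  })
  cbind(raw, do.call(cbind, extra))
}

# Windowed statistic over all windows of one channel.
# E: nw x L matrix of window contents in chronological column order.
# Every operation is row-independent so a one-window call is bit-identical
# to the corresponding row of a batch call (streaming contract).
window_stat <- function(E, stat, L) {
  switch(stat,
    mean = rowMeans(E),
    sd = {
      m <- rowMeans(E)
      sqrt(rowSums((E - m)^2) / (L - 1))
    },
    min = do.call(pmin, lapply(seq_len(L), function(j) E[, j])),
    max = do.call(pmax, lapply(seq_len(L), function(j) E[, j])),
    slope = {
      x <- seq_len(L) - (L + 1) / 2
      w <- x / sum(x * x)
      rowSums(E * rep(w, each = nrow(E)))
    },
    stop("unknown statistic: ", stat))
}

#' Extract windowed features
#'
#' Computes the catalogue's features for every window. All statistics are
#' evaluated with row-independent arithmetic, so extracting from a single
#' 10-sample buffer (as the streaming engine does) reproduces the batch
#' result bit for bit.
#'
#' @param channels Channel matrix from [build_channel_matrix()].
#' @param starts Window start indices from [make_windows()].
#' @param spec A [window_spec()].
#' @param catalogue Feature catalogue (default [feature_catalogue()]).
#' @return Numeric matrix `length(starts) x nrow(catalogue)`, columns in
#'   catalogue order.
#' @export
extract_features <- function(channels, starts, spec,
                             catalogue = feature_catalogue()) {
  if (any(!is.finite(channels))) {
    bad <- which(!is.finite(channels), arr.ind = TRUE)[1, ]
    stop("non-finite input sample in channel ", colnames(channels)[bad[2]],
         " at index ", bad[1])
  }
  L <- spec$samples_per_window
  nw <- length(starts)
  out <- matrix(0, nw, nrow(catalogue), dimnames = list(NULL, catalogue$name))
  idx <- outer(starts, 0:(L - 1L), "+")     # nw x L chronological indices
  for (ch in unique(catalogue$channel)) {
    E <- matrix(channels[, ch][idx], nw, L)
    for (r in which(catalogue$channel == ch)) {
      out[, r] <- window_stat(E, catalogue$stat[r], L)
    }
  }
  out
}

#' Fit a min-max scaler on training features
#'
#' @param X Training feature matrix.
#' @return Object of class `scaler_params`: per-feature `min` and `max`.
#'   Degenerate features (max == min) are flagged with a warning and mapped
#'   to 0 when applied.
#' @export
fit_scaler <- function(X) {
  if (nrow(X) == 0) stop("cannot fit a scaler on an empty training set")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  degen <- maxs == mins
  if (any(degen)) {
    warning("degenerate (constant) feature(s): ",
            paste(colnames(X)[degen], collapse = ", "), "; mapped to 0")
  }
  structure(list(min = mins, max = maxs, degenerate = degen),
            class = "scaler_params")
}

#' Apply a fitted min-max scaler
#'
#' Training columns land in [0, 1]; new data uses the stored training
#' parameters and may exit that range (no clipping).
#'
#' @param X Feature matrix (columns matching the scaler).
#' @param params A `scaler_params` from [fit_scaler()].
#' @return Scaled matrix.
#' @export
apply_scaler <- function(X, params) {
  rng <- params$max - params$min
  rng[params$degenerate] <- 1
  out <- (X - rep(params$min, each = nrow(X))) / rep(rng, each = nrow(X))
  if (any(params$degenerate)) out[, params$degenerate] <- 0
  out
}

# feature importance from a linear SVM: one-vs-one weight vectors aggregated
# as the sum of squared weights per feature
svm_feature_weights <- function(X, y, cost = 1) {
  fit <- tryCatch(
    e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("SVM failed to converge; ranking from a regularized linear fit")
    # squared-weight ranking from ridge-regularized least squares on +/-1
    Y <- outer(y, levels(y), "==") * 2 - 1
    XtX <- crossprod(X) + diag(1e-2, ncol(X))
    W <- solve(XtX, crossprod(X, Y))
    return(rowSums(W^2))
  }
  W <- crossprod(fit$SV, fit$coefs)   # p x (k-1) ovo aggregate
  rowSums(W^2)
}

# grouped k-fold assignment: participants are kept whole within a fold
grouped_folds <- function(groups, k, seed = 1) {
  ug <- unique(groups)
  k <- min(k, length(ug))
  set.seed(seed)
  fold_of_group <- sample(rep_len(seq_len(k), length(ug)))
  names(fold_of_group) <- ug
  fold_of_group[as.character(groups)]
}

#' Recursive feature elimination with a linear SVM
#'
#' Ranks features by iteratively dropping the one with the smallest
#' aggregated squared weight in a linear SVM refit on the survivors, then
#' scores every candidate subset size by participant-grouped k-fold CV
#' accuracy. The chosen subset is the CV argmax (ties favour the smaller
#' subset).
#'
#' @param X Scaled feature matrix.
#' @param y Window labels (factor).
#' @param groups Participant id per row (grouped CV folds).
#' @param sizes Candidate subset sizes to score (default all 1..p).
#' @param n_folds CV folds (default 5, capped at the number of groups).
#' @param cost SVM cost parameter.
#' @param seed Seed for fold assignment.
#' @return Object of class `selection_result`: `ranking` (feature names,
#'   best first), `cv_scores` (data frame size/score), `chosen` (names).
#' @export
rfe_select <- function(X, y, groups, sizes = NULL, n_folds = 5, cost = 1,
                       seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes for RFE")
  if (length(unique(groups)) < 2) stop("need at least 2 participants for RFE")
  p <- ncol(X)
  surviving <- colnames(X)
  elim_order <- character(0)
  while (length(surviving) > 1) {
    w <- svm_feature_weights(X[, surviving, drop = FALSE], y, cost)
    worst <- surviving[which.min(w)]
    elim_order <- c(elim_order, worst)
    surviving <- setdiff(surviving, worst)
  }
  ranking <- c(surviving, rev(elim_order))   # best first

  if (is.null(sizes)) sizes <- seq_len(p)
  folds <- grouped_folds(groups, n_folds, seed)
  cv <- vapply(sizes, function(k) {
    feats <- ranking[seq_len(k)]
    acc <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; te <- !tr
      fit <- e1071::svm(X[tr, feats, drop = FALSE], y[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, X[te, feats, drop = FALSE]) == y[te])
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  chosen_size <- sizes[which.max(cv)]        # which.max takes the first max
  structure(list(ranking = ranking,
                 cv_scores = data.frame(size = sizes, score = cv),
                 chosen = ranking[seq_len(chosen_size)]),
            class = "selection_result")
}
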