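# Sample-synchronous streaming inference. One logical tick per incoming
# sample (10 ms at 100 Hz); circular buffers hold the last 100 ms and a
# prediction is emitted for every sample once the buffer has filled. The
# arithmetic path (bias, fusion step, scaling, feature extraction,
# prediction) is shared with the offline classifier, so on identical input
# the two label sequences are identical — not merely close.

#' Initialise streaming state
#'
#' @param bundle A complete `onset_model` (classifier plus scaler, selected
#'   features, gyro scale and fusion settings).
#' @param preprocess `preprocess_params` for the incoming stream (bias of
#'   the sensors about to be streamed), e.g. from [estimate_bias()] on a
#'   static calibration capture.
#' @return Streaming state (an environment of class `stream_state`): empty
#'   buffers, identity fusion state, sample counter 0.
#' @export
stream_init <- function(bundle, preprocess) {
  for (part in c("model", "scaler", "features", "gyro_scale", "catalogue",
                 "window", "fusion_gain")) {
    if (is.null(bundle[[part]])) stop("incomplete model bundle: missing ", part)
  }
  if (!inherits(preprocess, "preprocess_params")) {
    stop("incomplete model bundle: missing preprocess params")
  }
  L <- bundle$window$samples_per_window
  chn <- c(signal_channels(),
           as.vector(vapply(names(sensor_names()),
                            function(s) paste0(c("sma_", "pitch_", "roll_"), s),
                            character(3))))
  state <- new.env(parent = emptyenv())
  state$bundle <- bundle
  state$preprocess <- preprocess
  state$L <- L
  state$buffer <- matrix(NA_real_, L, length(chn), dimnames = list(NULL, chn))
  state$tbuf <- rep(NA_real_, L)
  state$ptr <- 0L          # last written buffer row
  state$count <- 0L
  state$quat <- list(s1 = NULL, s2 = NULL, s3 = NULL)
  class(state) <- "stream_state"
  state
}

#' Reset a streaming state
#'
#' Empties the buffers and fusion state; the next emission again requires a
#' full buffer.
#'
#' @param state A `stream_state`.
#' @return The state, invisibly.
#' @export
stream_reset <- function(state) {
  state$buffer[] <- NA_real_
  state$tbuf[] <- NA_real_
  state$ptr <- 0L
  state$count <- 0L
  state$quat <- list(s1 = NULL, s2 = NULL, s3 = NULL)
  invisible(state)
}

#' Push one multi-sensor sample into the stream
#'
#' Applies the stored bias and gyro scale, advances the orientation filter
#' one step per sensor, appends the derived channel row to the circular
#' buffer and — from the moment the buffer first fills — emits exactly one
#' prediction per arriving sample, computed on the current 100 ms window.
#'
#' @param state A `stream_state` from [stream_init()].
#' @param sample Named numeric vector with the 18 raw channels
#'   (`s1_ax ... s3_gz`).
#' @param t Sample time stamp in seconds.
#' @return `NULL` while the buffer is filling, otherwise a list
#'   `(t, label, scores)`.
#' @export
push_sample <- function(state, sample, t = state$count / state$bundle$window$fs) {
  need <- signal_channels()
  if (!all(need %in% names(sample)) || any(!is.finite(sample[need]))) {
    warning("sample rejected: missing or non-finite channel value")
    return(NULL)
  }
  bundle <- state$bundle
  fs <- bundle$window$fs
  gb <- state$preprocess$gyro_bias
  ab <- state$preprocess$accel_bias
  row <- stats::setNames(numeric(ncol(state$buffer)), colnames(state$buffer))
  for (s in names(sensor_names())) {
    ach <- paste0(s, "_", c("ax", "ay", "az"))
    gch <- paste0(s, "_", c("gx", "gy", "gz"))
    acc <- sample[ach] - ab[ach]
    gyr <- sample[gch] - gb[gch]
    q <- if (state$count == 0L) fuse_init(unname(acc)) else
      fuse_step(state$quat[[s]], unname(gyr), unname(acc),
                bundle$fusion_gain, 1 / fs)
    state$quat[[s]] <- q
    ang <- orientation_angles(q)
    row[ach] <- acc
    row[gch] <- gyr / bundle$gyro_scale[gch]
    row[paste0("sma_", s)] <- abs(acc[1]) + abs(acc[2]) + abs(acc[3])
    row[paste0("pitch_", s)] <- ang[1, "pitch"]
    row[paste0("roll_", s)] <- ang[1, "roll"]
  }
  state$ptr <- state$ptr %% state$L + 1L
  state$buffer[state$ptr, ] <- row
  state$tbuf[state$ptr] <- t
  state$count <- state$count + 1L
  if (state$count < state$L) return(NULL)

  order_idx <- ((state$ptr + seq_len(state$L) - 1L) %% state$L) + 1L
  win <- state$buffer[order_idx, , drop = FALSE]
  X <- extract_features(win, 1L, bundle$window, bundle$catalogue)
  Xs <- apply_scaler(X, bundle$scaler)[, bundle$features, drop = FALSE]
  pred <- predict(bundle$model, Xs)
  list(t = t, label = as.character(pred$labels), scores = drop(pred$scores))
}

#' Replay a recorded log through the streaming engine
#'
#' @param bundle An `onset_model`.
#' @param log A `signal_log` of N samples.
#' @param preprocess Optional `preprocess_params`; estimated from the log's
#'   calibration window when `NULL`.
#' @return Data frame of N - L + 1 predictions (`t`, `label`, `score_*`),
#'   time-stamped with each window's last sample.
#' @export
run_stream <- function(bundle, log, preprocess = NULL) {
  if (is.null(preprocess)) preprocess <- estimate_bias(log, bundle$calibration_window)
  state <- stream_init(bundle, preprocess)
  raw <- as.matrix(log[signal_channels()])
  n <- nrow(raw)
  res_list <- vector("list", n)
  for (i in seq_len(n)) {
    res_list[[i]] <- push_sample(state, raw[i, ], log$t[i])
  }
  res_list <- res_list[!vapply(res_list, is.null, logical(1))]
  labels <- vapply(res_list, `[[`, character(1), "label")
  scores <- do.call(rbind, lapply(res_list, `[[`, "scores"))
  out <- data.frame(t = vapply(res_list, `[[`, numeric(1), "t"),
                    label = factor(labels, levels = bundle$classes))
  sc <- as.data.frame(scores)
  names(sc) <- paste0("score_", bundle$classes)
  cbind(out, sc)
}

#' Offline-vs-streaming equivalence report
#'
#' Classifies a log twice — batch (windows + vectorised prediction) and
#' streaming (sample-by-sample replay) — with the same model bundle and the
#' same bias estimate, and compares the two label sequences window by
#' window. Because both paths share one arithmetic implementation, the
#' contract is exact: any mismatch indicates a defect, and the macro-F1
#' difference must be exactly zero.
#'
#' @param bundle An `onset_model`.
#' @param log A `signal_log`.
#' @param labels The matching `label_track` (for the F1 computations).
#' @return Object of class `equivalence_report`: `n_windows`,
#'   `mismatch_count`, `mismatch_indices`, `f1_offline`, `f1_online`,
#'   `f1_diff`.
#' @export
compare_offline_online <- function(bundle, log, labels) {
  preprocess <- estimate_bias(log, bundle$calibration_window)
  off <- offline_predict(bundle, log, preprocess)
  on <- run_stream(bundle, log, preprocess)
  stopifnot(nrow(off) == nrow(on))
  mism <- which(as.character(off$label) != as.character(on$label))
  spec <- bundle$window
  starts <- make_windows(nrow(log), spec)
  truth <- window_labels(sample_labels(log, labels), starts, spec)
  f1_off <- class_metrics(confusion_matrix(truth, off$label))$macro_f1
  f1_on <- class_metrics(confusion_matrix(truth, on$label))$macro_f1
  structure(list(n_windows = nrow(off), mismatch_count = length(mism),
                 mismatch_indices = mism, f1_offline = f1_off,
                 f1_online = f1_on, f1_diff = f1_off - f1_on),
            class = "equivalence_report")
}

#' Debounce a prediction track into onset events
#'
#' A task-support controller should not switch on a single window: an onset
#' event is raised only after `n` consecutive identical predictions of a
#' class different from the previously confirmed one.
#'
#' @param labels Character/factor sequence of streaming predictions.
#' @param n Consecutive identical predictions required (default 5).
#' @return Data frame `index`, `class` of confirmed onset events (the index
#'   is the first window of each confirmed run).
#' @export
debounce_track <- function(labels, n = 5) {
  x <- as.character(labels)
  events <- list()
  current <- NA_character_
  run_class <- NA_character_; run_len <- 0L; run_start <- 1L
  for (i in seq_along(x)) {
    if (!identical(x[i], run_class)) {
      run_class <- x[i]; run_len <- 1L; run_start <- i
    } else {
      run_len <- run_len + 1L
    }
    if (run_len >= n && !identical(run_class, current)) {
      current <- run_class
      events[[length(events) + 1L]] <- data.frame(index = run_start,
                                                  class = run_class)
    }
  }
  if (length(events) == 0) {
    return(data.frame(index = integer(0), class = character(0)))
  }
  do.call(rbind, events)
}
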