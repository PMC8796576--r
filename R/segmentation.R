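# Sliding-window segmentation with majority-vote labelling and
# class balancing.

#' Sliding-window specification
#'
#' Defaults follow the recognition design: 100 ms windows with 90% overlap
#' at 100 Hz, i.e. 10 samples per window advanced by 1 sample (10 ms) — the
#' same cadence the streaming engine classifies at.
#'
#' @param length_ms Window length in milliseconds; `length_ms * fs / 1000`
#'   must be an integer >= 2.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param fs Sampling rate, Hz.
#' @return Object of class `window_spec` with `samples_per_window` and
#'   `step_samples`.
#' @export
window_spec <- function(length_ms = 100, overlap = 0.9, fs = 100) {
  L <- length_ms * fs / 1000
  if (abs(L - round(L)) > 1e-9 || L < 2) {
    stop("length_ms * fs / 1000 must be an integer >= 2")
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- as.integer(round(L))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  structure(list(length_ms = length_ms, overlap = overlap, fs = fs,
                 samples_per_window = L, step_samples = step),
            class = "window_spec")
}

#' Window start indices for a recording
#'
#' With `N` samples, window length `L` and step `S` the start indices are
#' `1, 1 + S, ...`, giving `floor((N - L) / S) + 1` windows.
#'
#' @param n_samples Number of samples in the recording.
#' @param spec A [window_spec()].
#' @return Integer vector of 1-based start indices (empty, with a warning,
#'   if the recording is shorter than one window).
#' @export
make_windows <- function(n_samples, spec) {
  L <- spec$samples_per_window; S <- spec$step_samples
  if (n_samples < L) {
    warning("recording shorter than one window: no windows produced")
    return(integer(0))
  }
  seq.int(1L, n_samples - L + 1L, by = S)
}

#' Majority-vote label for one window
#'
#' Returns the modal class of the per-sample labels. Ties are broken in
#' favour of the class of the last sample in the window (more generally, of
#' the tied class occurring latest), which biases transition windows toward
#' the new activity and so supports early onset detection.
#'
#' @param classes Factor (or character) of per-sample classes, chronological.
#' @return Single class name (character).
#' @export
label_window <- function(classes) {
  x <- as.character(classes)
  if (length(x) == 0) stop("empty sample-label sequence")
  counts <- table(x)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  last_pos <- vapply(top, function(cl) max(which(x == cl)), numeric(1))
  top[which.max(last_pos)]
}

#' Majority-vote labels for all windows of a recording
#'
#' @param sample_classes Per-sample class factor (see [sample_labels()]).
#' @param starts Window start indices from [make_windows()].
#' @param spec A [window_spec()].
#' @return Factor of window labels, levels `activity_classes()`.
#' @export
window_labels <- function(sample_classes, starts, spec) {
  L <- spec$samples_per_window
  codes <- as.integer(activity_factor(as.character(sample_classes)))
  k <- length(activity_classes())
  out <- integer(length(starts))
  for (j in seq_along(starts)) {
    idx <- codes[starts[j]:(starts[j] + L - 1L)]
    cnt <- tabulate(idx, k)
    mx <- max(cnt)
    top <- which(cnt == mx)
    if (length(top) == 1L) {
      out[j] <- top
    } else {
      # tie: latest-occurring tied class wins
      pos <- vapply(top, function(cl) max(which(idx == cl)), numeric(1))
      out[j] <- top[which.max(pos)]
    }
  }
  factor(activity_classes()[out], levels = activity_classes())
}

#' Down-sample windows to balance classes
#'
#' Training sets are balanced by removing windows uniformly at random from
#' the over-represented classes, never by duplicating. Applied to training
#' windows only; test windows keep their natural distribution.
#'
#' @param labels Factor of window labels.
#' @param seed Integer seed; identical seeds give identical retained sets.
#' @param n_per_class Optional cap on windows per class; default is the
#'   minimum class count. Values above a class's count keep all of them.
#' @param classes Classes that must all be present (default all 8).
#' @return Sorted integer indices of the retained windows.
#' @export
balance_classes <- function(labels, seed = 1, n_per_class = NULL,
                            classes = activity_classes()) {
  labels <- activity_factor(as.character(labels))
  counts <- table(labels)[classes]
  absent <- classes[is.na(counts) | counts == 0]
  if (length(absent) > 0) {
    stop("class(es) absent from training windows: ",
         paste(absent, collapse = ", "))
  }
  target <- if (is.null(n_per_class)) min(counts) else min(n_per_class, min(counts))
  set.seed(seed)
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > target) sort(sample(idx, target)) else idx
  }), use.names = FALSE)
  sort(keep)
}
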