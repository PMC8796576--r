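# CSV I/O for signal logs and label tracks.
#
# Log format: header t,s1_ax,...,s3_gz, one row per sample, times printed
# with 6 decimals (exact for a 100 Hz grid), signal values with full
# precision so a write/read round trip is bit-identical.

#' Write a signal log to CSV
#'
#' @param log A `signal_log` data frame (column `t` plus the 18 channels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_log <- function(log, path) {
  stopifnot(all(c("t", signal_channels()) %in% names(log)))
  cols <- c(sprintf("%.6f", log$t),
            vapply(signal_channels(),
                   function(ch) sprintf("%.17g", log[[ch]]), character(nrow(log))))
  m <- matrix(cols, nrow = nrow(log))
  lines <- c(paste(c("t", signal_channels()), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signal log from CSV
#'
#' Validates the header against the canonical column set and checks the
#' sampling grid: the streaming engine assumes one sample per fixed tick, so
#' any gap, duplicate or non-uniform spacing is an error.
#'
#' @param path CSV file written by [write_signal_log()].
#' @param fs Expected sampling rate, Hz.
#' @param participant_id Optional id to attach.
#' @return A `signal_log` data frame.
#' @export
read_signal_log <- function(path, fs = 100, participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", signal_channels())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  dt <- diff(df$t)
  if (nrow(df) > 1 && max(abs(dt - 1 / fs)) >= 1e-6) {
    stop("sampling error: time stamps are not a uniform ", fs, " Hz grid")
  }
  class(df) <- c("signal_log", "data.frame")
  attr(df, "fs") <- fs
  if (!is.null(participant_id)) attr(df, "participant_id") <- participant_id
  df
}

#' Write a label track to CSV
#'
#' @param labels A `label_track` data frame (`t_start`, `t_end`, `class`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(labels, path) {
  lines <- c("t_start,t_end,class_name",
             sprintf("%.6f,%.6f,%s", labels$t_start, labels$t_end,
                     as.character(labels$class)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a label track from CSV
#'
#' Checks that the intervals are an ordered, gap-free, overlap-free
#' partition starting at 0 and that every class name is known.
#'
#' @param path CSV file written by [write_label_track()].
#' @return A `label_track` data frame.
#' @export
read_label_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("t_start", "t_end", "class_name")
  if (!all(need %in% names(df))) {
    stop("format error: expected columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(t_start = df$t_start, t_end = df$t_end,
                    class = as.character(df$class_name))
  activity_factor(out$class)   # validates names
  if (any(out$t_end <= out$t_start)) stop("label intervals must have t_start < t_end")
  if (nrow(out) > 1 && max(abs(out$t_start[-1] - out$t_end[-nrow(out)])) > 1e-9) {
    stop("label intervals must partition the recording (no gaps/overlaps)")
  }
  class(out) <- c("label_track", "data.frame")
  out
}

#' Map interval labels onto sample times
#'
#' Intervals are half-open `[t_start, t_end)`: a sample lying exactly on a
#' boundary belongs to the later interval, so the first sample of a new
#' activity is labelled with the new activity.
#'
#' @param log A `signal_log` (or anything with a `t` column).
#' @param labels A `label_track` covering the log's time span.
#' @return Factor of per-sample classes, levels `activity_classes()`.
#' @export
sample_labels <- function(log, labels) {
  t <- log$t
  starts <- labels$t_start
  idx <- findInterval(t, starts)
  if (any(idx == 0) || any(t >= labels$t_end[nrow(labels)])) {
    stop("coverage error: label track does not cover all sample times")
  }
  activity_factor(as.character(labels$class[idx]))
}

#' Write a cohort to a directory
#'
#' Emits one log and one label CSV per participant plus a `manifest.csv`
#' with columns `participant_id,log_path,label_path,impaired_flag`.
#'
#' @param cohort An `imu_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(p) {
    id <- p$profile$participant_id
    lp <- file.path(dir, paste0(id, "_log.csv"))
    bp <- file.path(dir, paste0(id, "_labels.csv"))
    write_signal_log(p$log, lp)
    write_label_track(p$labels, bp)
    data.frame(participant_id = id, log_path = basename(lp),
               label_path = basename(bp),
               impaired_flag = isTRUE(p$profile$impaired))
  })
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$participant_id)) {
    stop("participant ids must be unique")
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return An `imu_cohort` list of `list(log, labels, profile)` entries
#'   (profiles carry only id and impaired flag).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    log <- read_signal_log(file.path(dir, manifest$log_path[i]),
                           participant_id = manifest$participant_id[i])
    labels <- read_label_track(file.path(dir, manifest$label_path[i]))
    list(log = log, labels = labels,
         profile = list(participant_id = manifest$participant_id[i],
                        impaired = manifest$impaired_flag[i]))
  })
  structure(out, class = "imu_cohort")
}
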