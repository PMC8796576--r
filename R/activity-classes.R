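#' The eight recognised activity classes
#'
#' Returns the fixed, ordered vector of activity-class names used throughout
#' the package. The order is part of the contract: class index `i` (0-based
#' `i - 1` for external consumers) always refers to the same activity, and
#' confusion matrices, one-hot targets and score columns all follow it.
#'
#' The transitions are split into an initiation phase and a settling phase:
#' `sit_to_stand` runs from the first forward lean of the trunk to seat-off,
#' `m_standing` ("motion of standing") from seat-off to a stable stance;
#' `stand_to_sit` and `m_sitting` mirror this for sitting down. `walking` is
#' straight-line gait, `turning` a 180-degree U-turn, and `standing` /
#' `sitting` are the motionless postures.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  c("sit_to_stand", "m_standing", "stand_to_sit", "m_sitting",
    "walking", "turning", "standing", "sitting")
}

#' Coerce labels to the canonical activity factor
#'
#' @param x Character vector (or factor) of activity-class names.
#' @return Factor with levels `activity_classes()`.
#' @export
activity_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), activity_classes())
  if (length(bad) > 0) {
    stop("unknown activity class(es): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = activity_classes())
}

#' IMU sensor identifiers
#'
#' Sensors are worn on the sternum and the middle of both outer thighs.
#' Column prefixes `s1`, `s2`, `s3` in a signal log map to this order.
#'
#' @return Named character vector `c(s1 = "sternum", s2 = "thigh_L", s3 = "thigh_R")`.
#' @export
sensor_names <- function() {
  c(s1 = "sternum", s2 = "thigh_L", s3 = "thigh_R")
}

# 18 raw channel names in canonical column order
signal_channels <- function() {
  as.vector(vapply(names(sensor_names()), function(s) {
    paste0(s, "_", c("ax", "ay", "az", "gx", "gy", "gz"))
  }, character(6)))
}

gyro_channels <- function() grep("_g[xyz]$", signal_channels(), value = TRUE)
accel_channels <- function() grep("_a[xyz]$", signal_channels(), value = TRUE)
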