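#' Read an IMU recording from CSV
#'
#' Expects a UTF-8 CSV with header columns \code{t, calf_id, ax, ay, az, gx,
#' gy, gz}; acceleration in g, angular velocity in deg/s, timestamps in
#' seconds. Rows exceeding the configured full-scale ranges are rejected
#' unless \code{clip = TRUE}, in which case they are clipped to the scale
#' bound.
#'
#' @param path path to the recording CSV.
#' @param config a \linkS4class{SensorConfig}.
#' @param clip clip out-of-scale samples instead of failing.
#' @return An \linkS4class{IMURecording}.
#' @export
#' @examples
#' rec <- simulateRecording(makeScenario("c1", 20, seed = 1))$recording
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' nSamples(rec2)
readRecording <- function(path, config = sensorConfig(), clip = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "calf_id", .imu_channels)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("recording format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(d$calf_id)
  if (length(ids) != 1)
    stop("recording integrity error: mixed calf_ids (",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  if (nrow(d) > 1 && any(diff(d$t) <= 0))
    stop("recording integrity error: timestamps not strictly increasing",
         call. = FALSE)
  acc <- as.matrix(d[c("ax", "ay", "az")])
  gyr <- as.matrix(d[c("gx", "gy", "gz")])
  if (clip) {
    acc <- pmin(pmax(acc, -config@accelScale), config@accelScale)
    gyr <- pmin(pmax(gyr, -config@gyroScale), config@gyroScale)
    d[c("ax", "ay", "az")] <- acc
    d[c("gx", "gy", "gz")] <- gyr
  } else {
    if (any(abs(acc) > config@accelScale))
      stop("recording integrity error: acceleration exceeds full scale of ",
           config@accelScale, " g", call. = FALSE)
    if (any(abs(gyr) > config@gyroScale))
      stop("recording integrity error: angular velocity exceeds full scale of ",
           config@gyroScale, " deg/s", call. = FALSE)
  }
  imuRecording(ids, d[c("t", .imu_channels)], fs = config@fs)
}

#' Write an IMU recording to CSV
#'
#' Inverse of \code{\link{readRecording}}; magnitude channels are not
#' written (they are derived).
#'
#' @param rec an \linkS4class{IMURecording}.
#' @param path output path.
#' @param digits significant digits written.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, digits = 8) {
  d <- rec@data[c("t", .imu_channels)]
  d <- cbind(t = signif(d$t, digits), calf_id = rec@calfId,
             signif(d[.imu_channels], digits))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavior annotation track from CSV
#'
#' Expects header columns \code{calf_id, behavior, tier, start_s, end_s}.
#' Behavior names must come from the ethogram vocabulary (or
#' \code{extraVocabulary}); within-tier overlapping intervals and
#' non-positive durations on the action/state tiers are rejected.
#'
#' @param path path to the annotation CSV.
#' @param extraVocabulary additional allowed behavior names.
#' @return An \linkS4class{AnnotationTrack}.
#' @export
readAnnotations <- function(path, extraVocabulary = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("calf_id", "behavior", "tier", "start_s", "end_s")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("annotation format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(d$calf_id)
  if (length(ids) != 1)
    stop("annotation integrity error: mixed calf_ids", call. = FALSE)
  vocab <- c(unlist(ethogramVocabulary(), use.names = FALSE), extraVocabulary)
  unknown <- setdiff(unique(d$behavior), vocab)
  if (length(unknown))
    stop("annotation vocabulary error: unknown behavior(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  annotationTrack(ids, d[c("behavior", "tier", "start_s", "end_s")],
                  extraVocabulary = extraVocabulary)
}

#' Write an annotation track to CSV
#'
#' @param track an \linkS4class{AnnotationTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(track, path) {
  iv <- track@intervals
  d <- cbind(calf_id = track@calfId, iv[c("behavior", "tier", "start_s", "end_s")])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
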