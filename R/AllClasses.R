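#' @import methods
NULL

#' Behavior vocabulary of the ethogram
#'
#' The six core behaviors recognised by the pipeline, split over three tiers:
#' feeding-related actions (\code{natural_suckling}, \code{feeding},
#' \code{rumination}), postural states (\code{lying}, \code{standing}) and
#' short events (\code{coughing}). Actions that match none of the tagged
#' action behaviors for the majority of a window are labelled
#' \code{"others"}.
#'
#' @return Named list of character vectors with elements \code{action},
#'   \code{state} and \code{event}.
#' @export
#' @examples
#' ethogramVocabulary()
ethogramVocabulary <- function() {
  list(
    action = c("natural_suckling", "feeding", "rumination"),
    state  = c("lying", "standing"),
    event  = c("coughing")
  )
}

ACTION_CLASSES <- c("natural_suckling", "rumination", "feeding", "others")
STATE_CLASSES  <- c("lying", "standing")
EVENT_CLASSES  <- c("non_coughing", "coughing")

.imu_channels <- c("ax", "ay", "az", "gx", "gy", "gz")

#' SensorConfig: sampling and scale configuration of the collar IMU
#'
#' @slot fs sampling frequency in Hz.
#' @slot accelScale full-scale range of the accelerometer in g.
#' @slot gyroScale full-scale range of the gyroscope in deg/s.
#' @slot noddingAxis gyroscope axis aligned with the head-nodding rotation
#'   (one of \code{"x"}, \code{"y"}, \code{"z"}); the suckling nodding
#'   oscillation appears on this channel.
#' @export
setClass("SensorConfig",
  representation(fs = "numeric", accelScale = "numeric",
                 gyroScale = "numeric", noddingAxis = "character"),
  prototype(fs = 25, accelScale = 4, gyroScale = 500, noddingAxis = "y"))

setValidity("SensorConfig", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@accelScale) != 1 || object@accelScale <= 0)
    msg <- c(msg, "accelScale must be positive")
  if (length(object@gyroScale) != 1 || object@gyroScale <= 0)
    msg <- c(msg, "gyroScale must be positive")
  if (!object@noddingAxis %in% c("x", "y", "z"))
    msg <- c(msg, "noddingAxis must be one of 'x', 'y', 'z'")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorConfig
#'
#' Defaults match a typical collar unit: 25 Hz sampling, +/-4 g accelerometer,
#' +/-500 deg/s gyroscope, nodding rotation on gyroscope y.
#'
#' @param fs sampling frequency in Hz.
#' @param accelScale accelerometer full scale in g.
#' @param gyroScale gyroscope full scale in deg/s.
#' @param noddingAxis gyroscope axis of the nodding rotation.
#' @return A \linkS4class{SensorConfig} object.
#' @export
#' @examples
#' sensorConfig()
sensorConfig <- function(fs = 25, accelScale = 4, gyroScale = 500,
                         noddingAxis = "y") {
  new("SensorConfig", fs = fs, accelScale = accelScale,
      gyroScale = gyroScale, noddingAxis = noddingAxis)
}

#' IMURecording: a per-calf six-axis IMU time series
#'
#' Holds one contiguous recording for one calf: timestamps \code{t} (seconds
#' since recording start), accelerometer channels \code{ax, ay, az} in g,
#' gyroscope channels \code{gx, gy, gz} in deg/s, and optionally the derived
#' magnitude channels \code{am} (acceleration magnitude) and \code{gm}
#' (angular-velocity magnitude) added by \code{\link{attachMagnitudes}}.
#'
#' @slot calfId character identifier of the calf.
#' @slot fs sampling frequency in Hz.
#' @slot data data.frame with columns \code{t, ax, ay, az, gx, gy, gz} and
#'   optionally \code{am, gm}; rows in time order with constant spacing 1/fs.
#' @export
setClass("IMURecording",
  representation(calfId = "character", fs = "numeric", data = "data.frame"))

setValidity("IMURecording", function(object) {
  msg <- character()
  d <- object@data
  need <- c("t", .imu_channels)
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("data must contain columns:", paste(need, collapse = ", ")))
  if (length(object@calfId) != 1 || is.na(object@calfId) || !nzchar(object@calfId))
    msg <- c(msg, "calfId must be a single non-empty string")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(d) < 1) msg <- c(msg, "recording must contain at least one sample")
  if (!length(msg) && nrow(d) > 1) {
    dt <- diff(d$t)
    if (any(dt <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    # regularity tolerance: |dt - 1/fs| <= 0.1/fs
    else if (any(abs(dt - 1 / object@fs) > 0.1 / object@fs))
      msg <- c(msg, "timestamps must be regular at 1/fs within 10% tolerance")
  }
  if (!length(msg) && any(d$t < 0)) msg <- c(msg, "timestamps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an IMURecording
#'
#' @param calfId calf identifier.
#' @param data data.frame with columns \code{t, ax, ay, az, gx, gy, gz}.
#' @param fs sampling frequency in Hz.
#' @return An \linkS4class{IMURecording}.
#' @export
imuRecording <- function(calfId, data, fs = 25) {
  new("IMURecording", calfId = as.character(calfId),
      fs = fs, data = as.data.frame(data))
}

#' AnnotationTrack: behavior intervals for one calf on three tiers
#'
#' Intervals are half-open in time, tiered as \code{action} (suckling,
#' feeding, rumination), \code{state} (lying, standing) or \code{event}
#' (coughing). Intervals within one tier may not overlap; event intervals may
#' be shorter than 2 s (coughs are), action/state intervals must have
#' positive duration.
#'
#' @slot calfId calf identifier.
#' @slot intervals data.frame with columns \code{behavior}, \code{tier},
#'   \code{start_s}, \code{end_s}.
#' @export
setClass("AnnotationTrack",
  representation(calfId = "character", intervals = "data.frame"))

.check_tier_overlaps <- function(iv) {
  bad <- character()
  for (tier in unique(iv$tier)) {
    x <- iv[iv$tier == tier, , drop = FALSE]
    x <- x[order(x$start_s), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start_s[-1] < x$end_s[-nrow(x)] - 1e-9))
      bad <- c(bad, tier)
  }
  bad
}

setValidity("AnnotationTrack", function(object) {
  msg <- character()
  iv <- object@intervals
  need <- c("behavior", "tier", "start_s", "end_s")
  if (!all(need %in% names(iv)))
    return(paste("intervals must contain columns:", paste(need, collapse = ", ")))
  if (length(object@calfId) != 1 || !nzchar(object@calfId))
    msg <- c(msg, "calfId must be a single non-empty string")
  if (nrow(iv)) {
    if (!all(iv$tier %in% c("action", "state", "event")))
      msg <- c(msg, "tier must be one of 'action', 'state', 'event'")
    vocab <- unlist(ethogramVocabulary(), use.names = FALSE)
    extra <- attr(iv, "extra_vocab")
    if (!all(iv$behavior %in% c(vocab, extra)))
      msg <- c(msg, paste("unknown behavior name(s):",
                          paste(setdiff(iv$behavior, c(vocab, extra)), collapse = ", ")))
    as_ <- iv$tier %in% c("action", "state")
    if (any(iv$end_s[as_] <= iv$start_s[as_]))
      msg <- c(msg, "action/state intervals must have end_s > start_s")
    if (any(iv$end_s < iv$start_s))
      msg <- c(msg, "intervals must have end_s >= start_s")
    bad <- .check_tier_overlaps(iv)
    if (length(bad))
      msg <- c(msg, paste("overlapping intervals within tier(s):",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTrack
#'
#' @param calfId calf identifier.
#' @param intervals data.frame with columns \code{behavior, tier, start_s,
#'   end_s}.
#' @param extraVocabulary optional character vector of additional allowed
#'   behavior names beyond the core ethogram.
#' @return An \linkS4class{AnnotationTrack}.
#' @export
annotationTrack <- function(calfId, intervals, extraVocabulary = NULL) {
  iv <- as.data.frame(intervals)
  if (!is.null(extraVocabulary)) attr(iv, "extra_vocab") <- extraVocabulary
  new("AnnotationTrack", calfId = as.character(calfId), intervals = iv)
}

#' FeatureTable: one feature row per window
#'
#' Couples window identity and labels with the named feature columns used by
#' one of the three classifiers (\code{model1} actions, \code{model2} states,
#' \code{model3} cough events).
#'
#' @slot data data.frame; identity/label columns first, then features.
#' @slot featureNames character vector naming the feature columns.
#' @slot modelTag one of \code{"model1"}, \code{"model2"}, \code{"model3"}.
#' @export
setClass("FeatureTable",
  representation(data = "data.frame", featureNames = "character",
                 modelTag = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!object@modelTag %in% c("model1", "model2", "model3"))
    msg <- c(msg, "modelTag must be 'model1', 'model2' or 'model3'")
  if (!all(object@featureNames %in% names(object@data)))
    msg <- c(msg, "all featureNames must be columns of data")
  fm <- object@data[object@featureNames]
  if (nrow(fm) && !all(vapply(fm, function(col) all(is.finite(col)), logical(1))))
    msg <- c(msg, "feature values must be finite (no missing cells)")
  if (length(msg)) msg else TRUE
})

featureTable <- function(data, featureNames, modelTag) {
  new("FeatureTable", data = as.data.frame(data),
      featureNames = featureNames, modelTag = modelTag)
}
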