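#' @include AllClasses.R
NULL

#' Accessors for calfIMU containers
#'
#' \code{calfId} returns the calf identifier; \code{samplingRate} the
#' sampling frequency in Hz; \code{sensorData} the sample data.frame of a
#' recording; \code{intervals} the interval data.frame of an annotation
#' track; \code{nSamples} and \code{duration} the length of a recording in
#' samples and seconds; \code{featureNames}, \code{featureMatrix},
#' \code{modelTag} and \code{tableData} the components of a
#' \linkS4class{FeatureTable}.
#'
#' @param object a calfIMU S4 object.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calfId", function(object) standardGeneric("calfId"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("sensorData", function(object) standardGeneric("sensorData"))
#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("modelTag", function(object) standardGeneric("modelTag"))
#' @rdname accessors
#' @export
setGeneric("tableData", function(object) standardGeneric("tableData"))

#' @rdname accessors
#' @export
setMethod("calfId", "IMURecording", function(object) object@calfId)
#' @rdname accessors
#' @export
setMethod("calfId", "AnnotationTrack", function(object) object@calfId)
#' @rdname accessors
#' @export
setMethod("samplingRate", "IMURecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SensorConfig", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("sensorData", "IMURecording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("intervals", "AnnotationTrack", function(object) object@intervals)
#' @rdname accessors
#' @export
setMethod("nSamples", "IMURecording", function(object) nrow(object@data))
#' @rdname accessors
#' @export
setMethod("duration", "IMURecording",
          function(object) (nrow(object@data) - 1) / object@fs)
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(object) object@featureNames)
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(object)
  as.matrix(object@data[object@featureNames]))
#' @rdname accessors
#' @export
setMethod("modelTag", "FeatureTable", function(object) object@modelTag)
#' @rdname accessors
#' @export
setMethod("tableData", "FeatureTable", function(object) object@data)

setMethod("show", "SensorConfig", function(object) {
  cat("SensorConfig: ", object@fs, " Hz, +/-", object@accelScale, " g, +/-",
      object@gyroScale, " deg/s, nodding axis g", object@noddingAxis, "\n",
      sep = "")
})

setMethod("show", "IMURecording", function(object) {
  n <- nrow(object@data)
  cat("IMURecording for calf '", object@calfId, "'\n", sep = "")
  cat("  ", n, " samples at ", object@fs, " Hz (",
      sprintf("%.2f", (n - 1) / object@fs), " s)\n", sep = "")
  cat("  channels: ", paste(setdiff(names(object@data), "t"), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "AnnotationTrack", function(object) {
  iv <- object@intervals
  cat("AnnotationTrack for calf '", object@calfId, "': ",
      nrow(iv), " intervals\n", sep = "")
  for (tier in c("action", "state", "event")) {
    x <- iv[iv$tier == tier, , drop = FALSE]
    if (nrow(x))
      cat("  ", tier, ": ", nrow(x), " bouts (",
          paste(unique(x$behavior), collapse = ", "), ")\n", sep = "")
  }
})

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable [", object@modelTag, "]: ", nrow(object@data),
      " windows x ", length(object@featureNames), " features\n", sep = "")
})
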