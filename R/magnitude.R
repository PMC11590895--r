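#' Euclidean magnitude of a triaxial signal
#'
#' Per-sample Euclidean norm across three equal-length axis series:
#' \eqn{\sqrt{x^2 + y^2 + z^2}}. Applied to the accelerometer this is the
#' acceleration magnitude Am; applied to the gyroscope, the angular-velocity
#' magnitude Gm. The magnitude is invariant to axis permutation and sign
#' flips, making it robust to collar rotation.
#'
#' @param x,y,z numeric series of equal length.
#' @return Non-negative numeric series of the same length.
#' @export
#' @examples
#' magnitude(3, 4, 0)   # 5
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("shape error: axis series must have equal lengths", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

#' Attach magnitude channels to a recording
#'
#' Adds \code{am = magnitude(ax, ay, az)} and \code{gm = magnitude(gx, gy,
#' gz)} as derived columns. Idempotent: magnitudes are recomputed from the
#' raw axes each call.
#'
#' @param rec an \linkS4class{IMURecording}.
#' @return The recording with \code{am} and \code{gm} populated.
#' @export
attachMagnitudes <- function(rec) {
  d <- rec@data
  d$am <- magnitude(d$ax, d$ay, d$az)
  d$gm <- magnitude(d$gx, d$gy, d$gz)
  rec@data <- d
  rec
}
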