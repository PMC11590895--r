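#' Peak-detection configuration for event windows
#'
#' Cough candidates are local maxima of the acceleration magnitude above a
#' threshold, with a minimum spacing between retained peaks. Both values are
#' tunable; the defaults are set so that the simulator's cough and bump
#' transients are detected while quiescent behavior yields no peaks.
#'
#' @param threshold acceleration-magnitude threshold in g.
#' @param minSeparationS minimum spacing between retained peaks in seconds.
#' @return A \code{PeakConfig} (classed list).
#' @export
peakConfig <- function(threshold = 1.3, minSeparationS = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (minSeparationS < 0) stop("minSeparationS must be >= 0", call. = FALSE)
  structure(list(threshold = threshold, minSeparationS = minSeparationS),
            class = "PeakConfig")
}

#' Segment a recording into fixed-length analysis windows
#'
#' Slides a window of \code{windowS} seconds (250 samples at 25 Hz) over the
#' recording with the given overlap (default 50\%, i.e. a 125-sample
#' stride). Trailing samples that do not fill a whole window are dropped,
#' preserving the fixed window geometry. Indices are 0-based and half-open.
#'
#' @param rec an \linkS4class{IMURecording}.
#' @param windowS window length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @return data.frame(calf_id, start_index, end_index, start_s); zero rows
#'   (with a warning) when the recording is shorter than one window.
#' @export
#' @examples
#' rec <- simulateRecording(makeScenario("c1", 40, seed = 2))$recording
#' nrow(segmentWindows(rec))  # floor((1000 - 250)/125) + 1 = 7
segmentWindows <- function(rec, windowS = 10, overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1)
  fs <- rec@fs
  wl <- round(windowS * fs)
  n <- nSamples(rec)
  if (n < wl) {
    warning("recording shorter than one window; returning no windows")
    return(data.frame(calf_id = character(), start_index = integer(),
                      end_index = integer(), start_s = numeric()))
  }
  step <- max(1L, round(wl * (1 - overlap)))
  starts <- seq.int(0L, n - wl, by = step)
  data.frame(calf_id = rec@calfId, start_index = starts,
             end_index = starts + wl, start_s = rec@data$t[starts + 1L])
}

.tier_occupancy <- function(iv, ws, we) {
  if (!nrow(iv)) return(numeric(0))
  ov <- pmax(0, pmin(iv$end_s, we) - pmax(iv$start_s, ws))
  tapply(ov, iv$behavior, sum)
}

#' Label analysis windows from an annotation track
#'
#' Implements the majority labeling rule: a window's action label is the
#' action-tier behavior covering strictly more than 50\% of the window
#' span, otherwise \code{"others"}; the state label is the state-tier
#' behavior occupying the strict majority of the window (an exact 50/50
#' split is resolved in favour of the earlier-starting state, with a
#' message). Actions and states are labelled in parallel because they
#' co-occur (e.g. rumination while lying).
#'
#' @param windows data.frame from \code{\link{segmentWindows}}.
#' @param track an \linkS4class{AnnotationTrack} whose state tier covers
#'   every window span.
#' @param fs sampling frequency used to convert indices to durations.
#' @return \code{windows} with \code{action_label} and \code{state_label}
#'   columns added.
#' @export
labelWindows <- function(windows, track, fs = 25) {
  iv <- track@intervals
  act <- iv[iv$tier == "action", , drop = FALSE]
  sta <- iv[iv$tier == "state", , drop = FALSE]
  nw <- nrow(windows)
  action_label <- character(nw)
  state_label <- character(nw)
  wlen <- (windows$end_index - windows$start_index) / fs
  for (i in seq_len(nw)) {
    ws <- windows$start_s[i]; we <- ws + wlen[i]
    occ_a <- .tier_occupancy(act, ws, we)
    action_label[i] <- if (length(occ_a) && max(occ_a) > wlen[i] / 2 + 1e-9)
      names(occ_a)[which.max(occ_a)] else "others"
    occ_s <- .tier_occupancy(sta, ws, we)
    if (!length(occ_s) || sum(occ_s) < wlen[i] - 1e-6)
      stop("labeling error: window [", ws, ", ", we,
           ") not covered by the state tier", call. = FALSE)
    top <- which(occ_s > max(occ_s) - 1e-9)
    if (length(top) > 1) {
      # exact tie: earlier-starting state wins
      starts <- vapply(names(occ_s)[top], function(b)
        min(sta$start_s[sta$behavior == b & sta$start_s < we &
                          sta$end_s > ws]), numeric(1))
      top <- top[which.min(starts)]
      message("state tie in window starting at ", ws,
              " s resolved to earlier-starting state")
    }
    state_label[i] <- names(occ_s)[top[1]]
  }
  windows$action_label <- action_label
  windows$state_label <- state_label
  windows
}

#' Detect acceleration-magnitude peaks
#'
#' Finds local maxima (strictly above the previous sample, not below the
#' next) of the acceleration magnitude that are at least \code{threshold},
#' then enforces the minimum spacing greedily by descending peak value
#' (ties broken toward the earlier index): whenever two candidates are
#' closer than the spacing, the larger one is retained.
#'
#' @param am non-negative acceleration-magnitude series.
#' @param cfg a \code{\link{peakConfig}}.
#' @param fs sampling frequency in Hz.
#' @return data.frame(peak_index, peak_value), peak_index 0-based, sorted
#'   by index.
#' @export
detectPeaks <- function(am, cfg = peakConfig(), fs = 25) {
  n <- length(am)
  if (n < 3) return(data.frame(peak_index = integer(), peak_value = numeric()))
  i <- 2:(n - 1)
  is_peak <- am[i - 1] < am[i] & am[i] >= am[i + 1] & am[i] >= cfg$threshold
  cand <- i[is_peak]                       # 1-based candidate positions
  if (!length(cand))
    return(data.frame(peak_index = integer(), peak_value = numeric()))
  minsep <- round(cfg$minSeparationS * fs)
  ord <- order(-am[cand], cand)            # by value desc, then earlier index
  kept <- integer()
  for (j in ord) {
    if (!length(kept) || all(abs(cand[j] - kept) >= minsep))
      kept <- c(kept, cand[j])
  }
  kept <- sort(kept)
  data.frame(peak_index = kept - 1L, peak_value = am[kept])
}

#' Extract peak-anchored event windows
#'
#' Builds one 31-sample window per detected peak: the peak sample plus the
#' 15 samples on each side. Peaks too close to the recording boundary to
#' supply 15 samples on both sides are dropped (with a message). When an
#' annotation track is supplied, a window is labelled \code{coughing} if
#' any event-tier cough interval intersects its time span, otherwise
#' \code{non_coughing}.
#'
#' @param rec an \linkS4class{IMURecording}.
#' @param peaks data.frame from \code{\link{detectPeaks}}.
#' @param track optional \linkS4class{AnnotationTrack} for labeling.
#' @param halfWidth samples on each side of the peak (15 gives 31 samples).
#' @return data.frame(calf_id, peak_index, peak_value, start_index,
#'   end_index[, label]); indices 0-based, half-open.
#' @export
extractEventWindows <- function(rec, peaks, track = NULL, halfWidth = 15) {
  n <- nSamples(rec)
  ok <- peaks$peak_index >= halfWidth & peaks$peak_index <= n - halfWidth - 1
  if (any(!ok))
    message(sum(!ok), " boundary peak(s) dropped (need ", halfWidth,
            " samples on each side)")
  p <- peaks[ok, , drop = FALSE]
  out <- data.frame(calf_id = rep(rec@calfId, nrow(p)),
                    peak_index = p$peak_index, peak_value = p$peak_value,
                    start_index = p$peak_index - halfWidth,
                    end_index = p$peak_index + halfWidth + 1L)
  if (!is.null(track)) {
    ev <- track@intervals
    ev <- ev[ev$tier == "event" & ev$behavior == "coughing", , drop = FALSE]
    t <- rec@data$t
    ws <- t[out$start_index + 1L]
    we <- t[out$end_index]                # time of last sample in window
    lab <- vapply(seq_len(nrow(out)), function(i)
      any(ev$start_s <= we[i] & ev$end_s >= ws[i]), logical(1))
    out$label <- ifelse(lab, "coughing", "non_coughing")
  }
  out
}
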