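#' Behavior signature for the synthetic IMU simulator
#'
#' A signature describes how one ethogram behavior shows up in the six-axis
#' signal. State-tier signatures (lying, standing) set the static gravity
#' orientation of the accelerometer and the per-channel noise level;
#' action-tier signatures (suckling, rumination, feeding) add periodic
#' oscillations on designated channels (head nodding on the nodding-axis
#' gyroscope, chewing on a gyroscope axis plus a small accelerometer
#' component); the event-tier cough signature is a short biphasic
#' acceleration transient.
#'
#' @param behavior behavior name.
#' @param tier \code{"action"}, \code{"state"} or \code{"event"}.
#' @param baseOrientation unit gravity vector on (ax, ay, az); states only.
#' @param accelNoiseSd,gyroNoiseSd white-noise SD (g, deg/s) contributed
#'   while the behavior is active.
#' @param osc data.frame with columns \code{channel}, \code{freq_hz},
#'   \code{amp} describing sinusoidal components, or NULL.
#' @param transient list with \code{duration_s} range and \code{peak_amp}
#'   range (g) for event behaviors, or NULL.
#' @return A \code{BehaviorSignature} (classed list).
#' @export
behaviorSignature <- function(behavior, tier, baseOrientation = NULL,
                              accelNoiseSd = 0, gyroNoiseSd = 0,
                              osc = NULL, transient = NULL) {
  if (!is.null(baseOrientation)) {
    if (length(baseOrientation) != 3 ||
        abs(sqrt(sum(baseOrientation^2)) - 1) > 1e-6)
      stop("baseOrientation must be a unit 3-vector", call. = FALSE)
  }
  if (!is.null(osc)) {
    stopifnot(all(c("channel", "freq_hz", "amp") %in% names(osc)))
    if (any(osc$freq_hz <= 0)) stop("osc_freq_hz must be positive", call. = FALSE)
  }
  structure(list(behavior = behavior, tier = tier,
                 baseOrientation = baseOrientation,
                 accelNoiseSd = accelNoiseSd, gyroNoiseSd = gyroNoiseSd,
                 osc = osc, transient = transient),
            class = "BehaviorSignature")
}

#' Default signature library
#'
#' Documented defaults chosen so the six core behaviors are separable by the
#' pipeline's own feature families: distinct gravity orientations and
#' variance levels for lying vs standing; a ~1.5 Hz nodding oscillation on
#' the nodding-axis gyroscope for natural suckling; chewing oscillations at
#' ~1.2 Hz (rumination) and ~2.2 Hz (feeding) on gyroscope x with a small
#' accelerometer component; a sharp ~0.5 s biphasic acceleration transient
#' for coughs. Amplitudes are in g / deg/s.
#'
#' @param config a \linkS4class{SensorConfig}; sets the nodding gyro channel.
#' @return Named list of \code{\link{behaviorSignature}} objects.
#' @export
defaultSignatureLibrary <- function(config = sensorConfig()) {
  nod <- paste0("g", config@noddingAxis)
  list(
    lying = behaviorSignature("lying", "state",
      baseOrientation = c(1, 0, 0), accelNoiseSd = 0.02, gyroNoiseSd = 3),
    standing = behaviorSignature("standing", "state",
      baseOrientation = c(0, 0, 1), accelNoiseSd = 0.05, gyroNoiseSd = 8),
    natural_suckling = behaviorSignature("natural_suckling", "action",
      gyroNoiseSd = 4,
      osc = data.frame(channel = nod, freq_hz = 1.5, amp = 80)),
    rumination = behaviorSignature("rumination", "action",
      gyroNoiseSd = 3,
      osc = data.frame(channel = c("gx", "az"), freq_hz = c(1.2, 1.2),
                       amp = c(40, 0.06))),
    feeding = behaviorSignature("feeding", "action",
      gyroNoiseSd = 5,
      osc = data.frame(channel = c("gx", "az"), freq_hz = c(2.2, 2.2),
                       amp = c(55, 0.08))),
    coughing = behaviorSignature("coughing", "event",
      transient = list(duration_s = c(0.4, 0.8), peak_amp = c(1.5, 2.6)))
  )
}

#' Construct a simulation scenario
#'
#' A scenario is one calf-day (or part of one): a calf id, a duration, a
#' bout schedule on the action and state tiers, optional cough event times,
#' and a seed. When no schedule is given a randomized one is drawn with
#' \code{\link{randomSchedule}}.
#'
#' @param calfId calf identifier.
#' @param duration_s scenario length in seconds.
#' @param schedule data.frame(behavior, tier, start_s, end_s) or NULL.
#' @param seed integer seed driving all noise in the simulated signal.
#' @return A \code{Scenario} (classed list).
#' @export
makeScenario <- function(calfId, duration_s, schedule = NULL, seed = 1) {
  if (is.null(schedule)) schedule <- randomSchedule(duration_s, seed = seed)
  st <- schedule[schedule$tier == "state", , drop = FALSE]
  st <- st[order(st$start_s), , drop = FALSE]
  if (nrow(st) == 0 || abs(st$start_s[1]) > 1e-9 ||
      abs(st$end_s[nrow(st)] - duration_s) > 1e-9 ||
      (nrow(st) > 1 && any(abs(st$start_s[-1] - st$end_s[-nrow(st)]) > 1e-9)))
    stop("scenario error: state tier must cover [0, duration_s] without gaps",
         call. = FALSE)
  ac <- schedule[schedule$tier == "action", , drop = FALSE]
  ac <- ac[order(ac$start_s), , drop = FALSE]
  if (nrow(ac) > 1 && any(ac$start_s[-1] < ac$end_s[-nrow(ac)] - 1e-9))
    stop("scenario error: action-tier bouts overlap", call. = FALSE)
  structure(list(calfId = as.character(calfId), duration_s = duration_s,
                 schedule = schedule, seed = as.integer(seed)),
            class = "Scenario")
}

#' Draw a randomized bout schedule
#'
#' States alternate lying/standing with log-normal bout durations; action
#' bouts (suckling, rumination, feeding) with log-normal durations are
#' separated by untagged gaps (which the labeling rule later turns into
#' "others" windows).
#'
#' @param duration_s schedule length in seconds.
#' @param seed integer seed.
#' @param actionProbs sampling probabilities for the three action behaviors.
#' @return data.frame(behavior, tier, start_s, end_s).
#' @export
randomSchedule <- function(duration_s, seed = 1,
                           actionProbs = c(natural_suckling = 0.3,
                                           rumination = 0.35,
                                           feeding = 0.35)) {
  set.seed(seed)
  rbout <- function(meanlog, sdlog, lo, hi)
    min(max(stats::rlnorm(1, meanlog, sdlog), lo), hi)
  # state tier: alternating lying/standing covering [0, duration]
  states <- character(); s0 <- numeric(); s1 <- numeric()
  cur <- sample(c("lying", "standing"), 1)
  t <- 0
  while (t < duration_s - 1e-9) {
    len <- if (cur == "lying") rbout(log(900), 0.5, 120, 3600)
           else rbout(log(700), 0.5, 120, 3600)
    e <- min(t + len, duration_s)
    states <- c(states, cur); s0 <- c(s0, t); s1 <- c(s1, e)
    t <- e
    cur <- if (cur == "lying") "standing" else "lying"
  }
  # action tier: gap, bout, gap, bout, ...
  acts <- character(); a0 <- numeric(); a1 <- numeric()
  t <- rbout(log(80), 0.6, 15, 400)
  while (t < duration_s - 45) {
    len <- rbout(log(150), 0.5, 30, 600)
    e <- min(t + len, duration_s)
    beh <- sample(names(actionProbs), 1, prob = actionProbs)
    acts <- c(acts, beh); a0 <- c(a0, t); a1 <- c(a1, e)
    t <- e + rbout(log(100), 0.6, 20, 600)
  }
  out <- data.frame(behavior = states, tier = "state", start_s = s0, end_s = s1)
  if (length(acts))
    out <- rbind(out, data.frame(behavior = acts, tier = "action",
                                 start_s = a0, end_s = a1))
  out
}

#' Inject rare cough events into a scenario
#'
#' Cough intervals shorter than 2 s are added on the event tier at
#' Poisson-process times (thinned so that no two coughs fall within 2 s of
#' each other), emulating the rarity of coughing over a day.
#'
#' @param scenario a \code{\link{makeScenario}} scenario.
#' @param ratePerHour expected coughs per hour (>= 0).
#' @param seed integer seed for the event draw.
#' @return The scenario with event-tier intervals appended.
#' @export
injectCoughs <- function(scenario, ratePerHour, seed = 1) {
  stopifnot(ratePerHour >= 0)
  set.seed(seed)
  dur <- scenario$duration_s
  n <- stats::rpois(1, ratePerHour * dur / 3600)
  if (n > 0) {
    times <- sort(stats::runif(n, 1, max(1, dur - 2)))
    # thin sequentially: keep a cough only if >= 2 s after the last kept one
    kept <- numeric()
    for (tt in times) if (!length(kept) || tt - kept[length(kept)] >= 2)
      kept <- c(kept, tt)
    lens <- stats::runif(length(kept), 0.4, 0.8)
    ev <- data.frame(behavior = "coughing", tier = "event",
                     start_s = kept, end_s = pmin(kept + lens, dur))
    scenario$schedule <- rbind(scenario$schedule, ev)
  }
  scenario
}

.osc_phase <- function() stats::runif(1, 0, 2 * pi)

#' Simulate an annotated six-axis IMU recording
#'
#' Renders a scenario's schedule into a sampled signal: the active state
#' sets the accelerometer's static gravity orientation and the noise floor;
#' active action bouts superimpose their oscillations (each bout with a
#' random phase); cough events add sharp biphasic acceleration transients
#' that raise the acceleration magnitude well above its baseline. Unlabelled
#' smooth "bump" transients (head knocks and shakes) are also generated so
#' that peak detection yields non-cough event windows; their rate is 2.8x
#' the cough count, mirroring the typical non-cough:cough event imbalance.
#' Fully deterministic given the scenario seed.
#'
#' @param scenario a \code{\link{makeScenario}} scenario.
#' @param library signature library, see \code{\link{defaultSignatureLibrary}}.
#' @param config a \linkS4class{SensorConfig}.
#' @param bumpFactor ratio of unlabelled bump transients to coughs.
#' @return list(recording = \linkS4class{IMURecording},
#'   track = \linkS4class{AnnotationTrack}).
#' @export
#' @examples
#' out <- simulateRecording(makeScenario("c1", 60, seed = 7))
#' out$recording
simulateRecording <- function(scenario, library = defaultSignatureLibrary(),
                              config = sensorConfig(), bumpFactor = 2.8) {
  fs <- config@fs
  n <- round(scenario$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sched <- scenario$schedule
  for (b in unique(sched$behavior)) {
    sig <- library[[b]]
    if (is.null(sig))
      stop("scenario error: no signature for behavior '", b, "'", call. = FALSE)
    if (!is.null(sig$osc) && any(sig$osc$freq_hz >= fs / 2))
      stop("scenario error: oscillation frequency at or above Nyquist",
           call. = FALSE)
  }
  set.seed(scenario$seed)
  ch <- matrix(0, n, 6, dimnames = list(NULL, .imu_channels))
  # state tier: gravity orientation + noise floor
  st <- sched[sched$tier == "state", , drop = FALSE]
  st <- st[order(st$start_s), , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    sig <- library[[st$behavior[i]]]
    idx <- which(t >= st$start_s[i] - 1e-12 & t < st$end_s[i] - 1e-12)
    m <- length(idx)
    if (!m) next
    ch[idx, 1:3] <- rep(sig$baseOrientation, each = m) +
      stats::rnorm(3 * m, 0, sig$accelNoiseSd)
    ch[idx, 4:6] <- stats::rnorm(3 * m, 0, sig$gyroNoiseSd)
  }
  # action tier: superimposed oscillations, random phase per bout
  ac <- sched[sched$tier == "action", , drop = FALSE]
  for (i in seq_len(nrow(ac))) {
    sig <- library[[ac$behavior[i]]]
    idx <- which(t >= ac$start_s[i] - 1e-12 & t < ac$end_s[i] - 1e-12)
    if (!length(idx)) next
    if (!is.null(sig$osc)) {
      for (k in seq_len(nrow(sig$osc))) {
        phase <- .osc_phase()
        ch[idx, sig$osc$channel[k]] <- ch[idx, sig$osc$channel[k]] +
          sig$osc$amp[k] * sin(2 * pi * sig$osc$freq_hz[k] * t[idx] + phase)
      }
    }
    if (sig$gyroNoiseSd > 0)
      ch[idx, 4:6] <- ch[idx, 4:6] + stats::rnorm(3 * length(idx), 0, sig$gyroNoiseSd)
  }
  # event tier: biphasic cough transients on ax
  ev <- sched[sched$tier == "event" & sched$behavior == "coughing", , drop = FALSE]
  csig <- library[["coughing"]]
  add_pulse <- function(center, durt, amp, shape) {
    idx <- which(abs(t - center) <= durt / 2)
    if (!length(idx)) return(invisible(NULL))
    u <- (t[idx] - center) / durt          # in [-1/2, 1/2]
    w <- cos(pi * u)^2                     # Hann taper
    p <- if (shape == "biphasic") amp * sin(2 * pi * u) * w else amp * w
    ch[idx, "ax"] <<- ch[idx, "ax"] + p
    invisible(NULL)
  }
  for (i in seq_len(nrow(ev))) {
    durt <- ev$end_s[i] - ev$start_s[i]
    amp <- stats::runif(1, csig$transient$peak_amp[1], csig$transient$peak_amp[2])
    add_pulse((ev$start_s[i] + ev$end_s[i]) / 2, durt, amp, "biphasic")
  }
  # unlabelled bump transients, kept >= 2 s clear of coughs and of each other
  n_bump <- stats::rpois(1, bumpFactor * max(nrow(ev), 1))
  if (n_bump > 0 && scenario$duration_s > 6) {
    cand <- sort(stats::runif(n_bump, 1.5, scenario$duration_s - 1.5))
    kept <- numeric()
    for (tt in cand) {
      if (nrow(ev) && min(abs(tt - (ev$start_s + ev$end_s) / 2)) < 2.5) next
      if (length(kept) && tt - kept[length(kept)] < 2) next
      kept <- c(kept, tt)
    }
    for (tt in kept)
      add_pulse(tt, stats::runif(1, 1.0, 1.6), stats::runif(1, 0.6, 1.6), "bump")
  }
  d <- data.frame(t = t, ch)
  rec <- imuRecording(scenario$calfId, d, fs = fs)
  track <- annotationTrack(scenario$calfId, sched[order(sched$tier, sched$start_s), ])
  list(recording = rec, track = track)
}

#' Simulate an annotated cohort of calves
#'
#' Draws an independent randomized scenario per calf (bout schedules from
#' the configured duration distributions, coughs at \code{coughRatePerHour})
#' and renders each to a recording plus annotation track. Reproducible by
#' seed; calf ids are unique.
#'
#' @param nCalves number of calves (>= 2).
#' @param dayLengthS recorded seconds per calf.
#' @param seed integer master seed.
#' @param coughRatePerHour expected coughs per hour per calf.
#' @param library,config passed to \code{\link{simulateRecording}}.
#' @return List of per-calf lists with elements \code{recording},
#'   \code{track}, \code{scenario}.
#' @export
simulateCohort <- function(nCalves, dayLengthS, seed = 1,
                           coughRatePerHour = 6,
                           library = defaultSignatureLibrary(),
                           config = sensorConfig()) {
  if (nCalves < 2)
    stop("argument error: nCalves must be at least 2", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * nCalves)
  lapply(seq_len(nCalves), function(i) {
    id <- sprintf("calf%02d", i)
    sc <- makeScenario(id, dayLengthS, seed = seeds[2 * i - 1])
    sc <- injectCoughs(sc, coughRatePerHour, seed = seeds[2 * i])
    out <- simulateRecording(sc, library = library, config = config)
    list(recording = out$recording, track = out$track, scenario = sc)
  })
}
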