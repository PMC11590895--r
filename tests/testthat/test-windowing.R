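test_that("segmentWindows enumerates 250-sample windows at the 125 stride", {
  rec <- make_recording(1000)
  w <- segmentWindows(rec)
  # brute-force enumeration of valid starts at stride 125
  starts <- integer()
  s <- 0L
  while (s + 250 <= 1000) { starts <- c(starts, s); s <- s + 125L }
  expect_equal(w$start_index, starts)            # 0, 125, ..., 750
  expect_equal(nrow(w), 7)
  expect_true(all(w$end_index - w$start_index == 250))
  expect_true(all(w$end_index <= 1000))
  expect_equal(diff(w$start_index), rep(125, 6))

  expect_equal(nrow(segmentWindows(make_recording(250))), 1)
  expect_warning(w0 <- segmentWindows(make_recording(200)), "shorter")
  expect_equal(nrow(w0), 0)
})

test_that("non-default window length and overlap follow the count formula", {
  rec <- make_recording(1000)
  for (ov in c(0, 0.25, 0.5)) {
    for (ws in c(4, 10)) {
      wl <- ws * 25
      step <- round(wl * (1 - ov))
      w <- segmentWindows(rec, ws, ov)
      expect_equal(nrow(w), floor((1000 - wl) / step) + 1)
      expect_true(all(diff(w$start_index) == step))
    }
  }
})

make_track <- function(action_df = NULL, state = "lying", dur = 100) {
  iv <- data.frame(behavior = state, tier = "state", start_s = 0, end_s = dur)
  if (!is.null(action_df)) iv <- rbind(iv, action_df)
  annotationTrack("c1", iv)
}

test_that("majority labeling follows the strict >50% rule on both tiers", {
  w <- data.frame(calf_id = "c1", start_index = 0L, end_index = 250L,
                  start_s = 0)
  # rumination for 6 of 10 s while lying -> (rumination, lying)
  tr <- make_track(data.frame(behavior = "rumination", tier = "action",
                              start_s = 2, end_s = 8))
  lw <- labelWindows(w, tr)
  expect_equal(lw$action_label, "rumination")
  expect_equal(lw$state_label, "lying")

  # feeding for only 4 of 10 s while standing -> (others, standing)
  tr <- make_track(data.frame(behavior = "feeding", tier = "action",
                              start_s = 0, end_s = 4), state = "standing")
  lw <- labelWindows(w, tr)
  expect_equal(lw$action_label, "others")
  expect_equal(lw$state_label, "standing")

  # exactly 5.000 of 10 s is NOT a majority -> others
  tr <- make_track(data.frame(behavior = "natural_suckling", tier = "action",
                              start_s = 0, end_s = 5))
  expect_equal(labelWindows(w, tr)$action_label, "others")

  # strictly more than half by a hair -> the action wins
  tr <- make_track(data.frame(behavior = "natural_suckling", tier = "action",
                              start_s = 0, end_s = 5.2))
  expect_equal(labelWindows(w, tr)$action_label, "natural_suckling")
})

test_that("state labeling takes the strict majority, ties to earlier state", {
  w <- data.frame(calf_id = "c1", start_index = 0L, end_index = 250L,
                  start_s = 0)
  tr <- annotationTrack("c1", data.frame(
    behavior = c("lying", "standing"), tier = "state",
    start_s = c(0, 4), end_s = c(4, 100)))
  expect_equal(labelWindows(w, tr)$state_label, "standing")

  tr50 <- annotationTrack("c1", data.frame(
    behavior = c("standing", "lying"), tier = "state",
    start_s = c(0, 5), end_s = c(5, 100)))
  expect_message(lw <- labelWindows(w, tr50), "tie")
  expect_equal(lw$state_label, "standing")       # earlier-starting state

  # missing state coverage is an error
  tr_gap <- annotationTrack("c1", data.frame(
    behavior = "lying", tier = "state", start_s = 0, end_s = 6))
  expect_error(labelWindows(w, tr_gap), "labeling error")
})

test_that("every window receives exactly one action and one state label", {
  out <- simulateRecording(makeScenario("c1", 300, seed = 13))
  w <- labelWindows(segmentWindows(out$recording), out$track)
  expect_false(anyNA(w$action_label))
  expect_false(anyNA(w$state_label))
  expect_true(all(w$action_label %in%
                    c("natural_suckling", "rumination", "feeding", "others")))
  expect_true(all(w$state_label %in% c("lying", "standing")))
})

test_that("windows aligned to bout boundaries label with the bout behavior", {
  sched <- rbind(
    data.frame(behavior = "lying", tier = "state", start_s = 0, end_s = 100),
    data.frame(behavior = "rumination", tier = "action",
               start_s = 0, end_s = 50),
    data.frame(behavior = "feeding", tier = "action",
               start_s = 50, end_s = 100))
  out <- simulateRecording(makeScenario("c1", 100, sched, seed = 3))
  w <- labelWindows(segmentWindows(out$recording, overlap = 0), out$track)
  expected <- ifelse(w$start_s < 50, "rumination", "feeding")
  expect_equal(w$action_label, expected)
})

test_that("detectPeaks finds thresholded local maxima with spacing", {
  am <- rep(0, 500); am[101] <- 3
  p <- detectPeaks(am, peakConfig(threshold = 2, minSeparationS = 1), fs = 25)
  expect_equal(p$peak_index, 100L)
  expect_equal(p$peak_value, 3)

  expect_equal(nrow(detectPeaks(rep(0.5, 300), peakConfig(1.3, 1), 25)), 0)

  # two candidates 8 samples apart under a 15-sample separation: larger wins
  am <- rep(0, 300); am[101] <- 2.5; am[109] <- 3.0
  p <- detectPeaks(am, peakConfig(2, 15 / 25), fs = 25)
  expect_equal(p$peak_index, 108L)
})

test_that("detectPeaks equals the brute-force spacing oracle", {
  set.seed(77)
  for (rep_i in 1:8) {
    n <- sample(200:2000, 1)
    am <- abs(rnorm(n, 1, 0.25)) + 2 * rbinom(n, 1, 0.01)
    cfg <- peakConfig(threshold = 1.6,
                      minSeparationS = sample(c(0.2, 0.6, 1), 1))
    p <- detectPeaks(am, cfg, fs = 25)
    expect_equal(p$peak_index,
                 oracle_peaks(am, cfg$threshold, round(cfg$minSeparationS * 25)))
  }
})

test_that("event windows hold 31 samples, 15 on each side of the peak", {
  rec <- make_recording(1000)
  peaks <- data.frame(peak_index = c(100L, 10L, 990L), peak_value = 2)
  expect_message(ew <- extractEventWindows(rec, peaks), "boundary")
  expect_equal(nrow(ew), 1)                      # boundary peaks dropped
  expect_equal(ew$start_index, 85L)
  expect_equal(ew$end_index, 116L)
  expect_equal(ew$end_index - ew$start_index, 31L)
})

test_that("event windows are labelled by cough-interval intersection", {
  rec <- make_recording(1000)
  track <- annotationTrack("c1", rbind(
    data.frame(behavior = "standing", tier = "state", start_s = 0, end_s = 40),
    data.frame(behavior = "coughing", tier = "event",
               start_s = 4.0, end_s = 4.6)))
  peaks <- data.frame(peak_index = c(103L, 500L), peak_value = 2)
  ew <- extractEventWindows(rec, peaks, track)
  # window at peak 103 spans t = 3.52..4.72 s, intersecting the cough
  expect_equal(ew$label, c("coughing", "non_coughing"))

  # independent interval-intersection oracle over a grid of peaks
  for (pk in seq(50L, 950L, by = 90L)) {
    ewi <- extractEventWindows(rec, data.frame(peak_index = pk,
                                               peak_value = 1), track)
    ws <- (pk - 15) / 25; we <- (pk + 15) / 25
    expect_equal(ewi$label == "coughing", 4.0 <= we && 4.6 >= ws)
  }
})
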