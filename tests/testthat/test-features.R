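test_that("dominantFrequency recovers pure and mixed sinusoids", {
  fs <- 25; t <- (0:249) / fs
  expect_equal(unname(dominantFrequency(sin(2 * pi * 2 * t), fs)["freq"]), 2)
  expect_equal(dominantFrequency(rep(3.7, 100), fs),
               c(freq = 0, power = 0))
  x <- sin(2 * pi * 1 * t) + 3 * sin(2 * pi * 5 * t)
  expect_equal(unname(dominantFrequency(x, fs)["freq"]), 5)
  expect_error(dominantFrequency(1, fs), "argument error")
})

test_that("dominantFrequency equals the naive O(N^2) DFT sum", {
  set.seed(5)
  for (n in c(16, 50, 128, 256)) {
    x <- rnorm(n) + sin(2 * pi * 3 * (0:(n - 1)) / n)
    got <- dominantFrequency(x, 25)
    want <- naive_dominant_frequency(x, 25)
    expect_equal(got["freq"], want["freq"])
    expect_equal(got["power"], want["power"], tolerance = 1e-9)
  }
})

test_that("off-bin sinusoids are recovered within one bin width", {
  fs <- 25; n <- 250; t <- (0:(n - 1)) / fs
  for (f0 in c(1.23, 2.71, 4.03)) {
    got <- dominantFrequency(sin(2 * pi * f0 * t), fs)["freq"]
    expect_lt(abs(got - f0), fs / n + 1e-12)
  }
})

test_that("signalIQR follows the linear-interpolation quantile rule", {
  expect_equal(signalIQR(rep(2, 10)), 0)
  expect_equal(signalIQR(1:100), 49.5)
  expect_equal(signalIQR(1:100), oracle_iqr(1:100))
  set.seed(6)
  x <- rnorm(137)
  expect_equal(signalIQR(x), oracle_iqr(x))
  expect_equal(signalIQR(x + 17.3), signalIQR(x))  # translation invariance
  expect_equal(signalIQR(3 * x), 3 * signalIQR(x)) # scale covariance
  expect_error(signalIQR(numeric(0)), "argument error")
})

test_that("zeroCrossings counts mean-centered sign changes", {
  expect_equal(zeroCrossings(c(1, -1, 1, -1)), 3)
  expect_equal(zeroCrossings(1:10), 1)   # centered ramp crosses once
  expect_equal(zeroCrossings(rep(5, 20)), 0)
  # exact zeros (mean-zero inputs) inherit the previous nonzero sign:
  # a zero lying inside a sign change still yields exactly one crossing...
  expect_equal(zeroCrossings(c(-2, 0, 2, 0)), 1)
  # ...and a touch of zero without sign reversal yields none
  expect_equal(zeroCrossings(c(-1, 0, -1, 1, 1)), 1)
  expect_equal(zeroCrossings(c(1, 0, 1, -1, -1)), 1)
  # affine invariance (positive scale) after centering
  set.seed(7)
  x <- rnorm(200)
  expect_equal(zeroCrossings(2.5 * x + 3), zeroCrossings(x))
})

test_that("gradientSeries is the forward difference over dt", {
  expect_equal(gradientSeries(seq(0, 10, by = 2), 0.04), rep(50, 5))
  expect_equal(gradientSeries(rep(1, 30), 0.04), rep(0, 29))
  expect_length(gradientSeries(rnorm(250), 0.04), 249)
  expect_error(gradientSeries(rnorm(10), 0), "argument error")
  expect_error(gradientSeries(3, 0.04), "argument error")
})

test_that("extractFeatures computes the full 96-column grid deterministically", {
  out <- simulateRecording(makeScenario("c1", 120, seed = 10))
  rec <- attachMagnitudes(out$recording)
  w <- labelWindows(segmentWindows(rec), out$track)
  ft <- extractFeatures(rec, w, "model1")
  expect_s4_class(ft, "FeatureTable")
  expect_length(featureNames(ft), 8 * 12)
  expect_true(all(is.finite(featureMatrix(ft))))

  # two identical windows produce identical rows (purity)
  w2 <- w[c(1, 1), ]
  ft2 <- extractFeatures(rec, w2, "model1")
  expect_equal(featureMatrix(ft2)[1, ], featureMatrix(ft2)[2, ])

  # batched features agree with the scalar operations
  i <- 3
  sl <- sensorData(rec)$gy[(w$start_index[i] + 1):(w$end_index[i])]
  expect_equal(unname(featureMatrix(ft)[i, "gy_mean"]), mean(sl))
  expect_equal(unname(featureMatrix(ft)[i, "gy_iqr"]), signalIQR(sl))
  expect_equal(unname(featureMatrix(ft)[i, "gy_zero_crossings"]),
               as.numeric(zeroCrossings(sl)))
  expect_equal(unname(featureMatrix(ft)[i, "gy_dom_freq"]),
               unname(dominantFrequency(sl, 25)["freq"]))
  g <- gradientSeries(sl, 1 / 25)
  expect_equal(unname(featureMatrix(ft)[i, "gy_grad_max_abs"]), max(abs(g)))
  expect_equal(unname(featureMatrix(ft)[i, "gy_grad_sd"]), sd(g))

  expect_error(extractFeatures(rec, w[0, ], "model1"), "argument error")
  wbad <- rbind(w[1:2, ], transform(w[3, ], end_index = end_index - 10))
  expect_error(extractFeatures(rec, wbad, "model1"), "shape error")
})

test_that("a pure-tone gyro window yields its frequency as gy_dom_freq", {
  n <- 500; t <- (0:(n - 1)) / 25
  d <- data.frame(t = t, ax = 0, ay = 0, az = 1,
                  gx = 0, gy = 30 * sin(2 * pi * 1.5 * t), gz = 0)
  rec <- imuRecording("c1", d)
  w <- data.frame(calf_id = "c1", start_index = 0L, end_index = 250L,
                  start_s = 0)
  ft <- extractFeatures(rec, w, "model1")
  expect_lt(abs(featureMatrix(ft)[1, "gy_dom_freq"] - 1.5), 25 / 250 + 1e-12)
})

test_that("dropCorrelated removes duplicates and constants, keeps noise", {
  set.seed(8)
  n <- 500
  f <- rnorm(n)
  d <- data.frame(calf_id = "c1", label = "x",
                  a = f, b = 2 * f, c = rnorm(n), k = rep(1, n))
  ft <- calfIMU:::featureTable(d, c("a", "b", "c", "k"), "model1")
  res <- dropCorrelated(ft, 0.9)
  expect_equal(res$report$surviving, c("a", "c"))      # b ~ a dropped, k constant
  expect_equal(res$report$dropped_correlated$dropped, "b")
  expect_equal(res$report$dropped_correlated$r, 1)
  expect_equal(res$report$dropped_constant, "k")
  # partition invariant
  expect_setequal(c(res$report$surviving, res$report$dropped_correlated$dropped,
                    res$report$dropped_constant), c("a", "b", "c", "k"))

  # mutually independent noise survives intact at threshold 0.9
  d2 <- as.data.frame(matrix(rnorm(n * 6), n))
  names(d2) <- paste0("f", 1:6)
  ft2 <- calfIMU:::featureTable(cbind(calf_id = "c1", d2),
                                paste0("f", 1:6), "model1")
  expect_length(dropCorrelated(ft2, 0.9)$report$surviving, 6)
})

test_that("selectByImportance keeps informative features, drops pure noise", {
  set.seed(9)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  d <- data.frame(calf_id = "c1",
                  label = ifelse(f1 > median(f1), "a", "b"),
                  f1 = f1, f2 = f2)
  ft <- calfIMU:::featureTable(d, c("f1", "f2"), "model3")
  res <- selectByImportance(ft, "label", seed = 1)
  expect_true("f1" %in% res$report$surviving)
  expect_gt(res$report$importance[["f1"]], 0)
  imp_f2 <- res$report$importance[["f2"]]
  expect_lt(imp_f2, res$report$importance[["f1"]] / 10)

  # topK = all leaves the table unchanged; topK too large errors
  res_all <- selectByImportance(ft, "label", topK = 2, seed = 1)
  expect_equal(featureNames(res_all$table), c("f1", "f2"))
  expect_error(selectByImportance(ft, "label", topK = 3), "argument error")
  # single-class labels rejected
  d$label <- "a"
  ft1c <- calfIMU:::featureTable(d, c("f1", "f2"), "model3")
  expect_error(selectByImportance(ft1c, "label"), "argument error")
})

test_that("selection never increases the feature count and partitions it", {
  out <- simulateRecording(makeScenario("c1", 200, seed = 12))
  rec <- attachMagnitudes(out$recording)
  ft <- extractFeatures(rec, labelWindows(segmentWindows(rec), out$track),
                        "model2")
  dc <- dropCorrelated(ft, 0.9)
  expect_lte(length(featureNames(dc$table)), length(featureNames(ft)))
  expect_setequal(
    c(dc$report$surviving, dc$report$dropped_correlated$dropped,
      dc$report$dropped_constant),
    featureNames(ft))
})
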