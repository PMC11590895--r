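FEATURE_STATS <- c("mean", "var", "sd", "min", "max", "iqr", "zero_crossings",
                   "dom_freq", "dom_power", "grad_mean_abs", "grad_max_abs",
                   "grad_sd")
FEATURE_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "am", "gm")

#' Dominant frequency of a window by discrete Fourier transform
#'
#' Computes the DFT \eqn{X[k] = \sum_n x[n] e^{-j 2\pi k n / N}} of the
#' mean-removed series and returns the frequency \eqn{k \cdot fs / N} of the
#' bin with maximal power \eqn{|X[k]|^2} over \eqn{1 \le k \le
#' \lfloor N/2 \rfloor}, together with that power. The DC bin and the upper
#' half-spectrum are excluded: the statistic targets periodicity (head
#' nodding, chewing), which DC is not. An all-constant series returns
#' \code{c(freq = 0, power = 0)}.
#'
#' @param x numeric series, length >= 2.
#' @param fs sampling frequency in Hz.
#' @return named numeric vector \code{c(freq, power)}.
#' @export
#' @examples
#' t <- (0:249) / 25
#' dominantFrequency(sin(2 * pi * 2 * t), 25)["freq"]  # 2 Hz
dominantFrequency <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop("argument error: series length must be >= 2", call. = FALSE)
  xc <- x - mean(x)
  X <- stats::fft(xc)
  kmax <- floor(n / 2)
  pw <- Mod(X[2:(kmax + 1)])^2
  if (max(pw) <= n * 1e-24) return(c(freq = 0, power = 0))
  k <- which.max(pw)
  c(freq = k * fs / n, power = pw[k])
}

#' Interquartile range of a window
#'
#' Q3 - Q1 under the linear-interpolation quantile rule (type 7), the
#' repetitive-movement spread statistic used for chewing behaviors.
#'
#' @param x numeric series, length >= 1.
#' @return Non-negative scalar.
#' @export
signalIQR <- function(x) {
  if (!length(x)) stop("argument error: empty series", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Zero crossings of a mean-centered window
#'
#' Counts sign changes \eqn{x[i] \cdot x[i+1] < 0} of the series after
#' subtracting its mean; samples that are exactly zero inherit the previous
#' nonzero sign, so a touch of zero without sign reversal does not count.
#'
#' @param x numeric series, length >= 2.
#' @return Integer count.
#' @export
zeroCrossings <- function(x) {
  if (length(x) < 2) stop("argument error: series length must be >= 2", call. = FALSE)
  c0 <- x - mean(x)
  s <- sign(c0)
  # zeros inherit the previous nonzero sign
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] * s[-length(s)] < 0)
}

#' Forward-difference gradient of a signal
#'
#' \eqn{G[n] = (x[n+1] - x[n]) / \Delta t}; captures the short, rapid
#' movements characteristic of coughs. Returns N - 1 values.
#'
#' @param x numeric series, length >= 2.
#' @param dt sampling interval in seconds (> 0).
#' @return Numeric series of length \code{length(x) - 1}.
#' @export
gradientSeries <- function(x, dt) {
  if (length(x) < 2) stop("argument error: series length must be >= 2", call. = FALSE)
  if (dt <= 0) stop("argument error: dt must be > 0", call. = FALSE)
  diff(x) / dt
}

# all 12 statistics for one channel over a window matrix (rows = windows)
.batch_channel_features <- function(M, fs) {
  n <- nrow(M); L <- ncol(M); dt <- 1 / fs
  mu <- rowMeans(M)
  v <- rowSums((M - mu)^2) / (L - 1)
  # spectra for all windows at once (columns of the transposed matrix)
  X <- stats::mvfft(t(M - mu))
  kmax <- floor(L / 2)
  pw <- Mod(X[2:(kmax + 1), , drop = FALSE])^2
  kstar <- max.col(t(pw), ties.method = "first")
  dom_p <- pw[cbind(kstar, seq_len(n))]
  zero_spec <- dom_p <= L * 1e-24
  G <- (M[, -1, drop = FALSE] - M[, -L, drop = FALSE]) / dt
  gmu <- rowMeans(G)
  cbind(
    mean = mu, var = v, sd = sqrt(v),
    min = apply(M, 1, min), max = apply(M, 1, max),
    iqr = apply(M, 1, signalIQR),
    zero_crossings = vapply(seq_len(n), function(i) zeroCrossings(M[i, ]), integer(1)),
    dom_freq = ifelse(zero_spec, 0, kstar * fs / L),
    dom_power = ifelse(zero_spec, 0, dom_p),
    grad_mean_abs = rowMeans(abs(G)),
    grad_max_abs = apply(abs(G), 1, max),
    grad_sd = sqrt(rowSums((G - gmu)^2) / (ncol(G) - 1))
  )
}

#' Extract the feature grid for a set of windows
#'
#' Computes the full statistic-by-channel grid — 12 statistics (mean,
#' variance, SD, min, max, IQR, zero crossings, dominant frequency and its
#' power, and mean/max/SD of the absolute signal gradient) for each of the
#' 8 channels (six axes plus the two magnitudes) — giving 96 named feature
#' columns per window. Frequency features thus cover the nodding-axis
#' gyroscope and both magnitudes, and gradient features cover every
#' channel. Extraction is pure: the same window always yields the same row.
#'
#' @param rec an \linkS4class{IMURecording} (magnitudes attached if absent).
#' @param windows window manifest from \code{\link{labelWindows}} or
#'   \code{\link{extractEventWindows}} (uniform window length required).
#' @param modelTag \code{"model1"}, \code{"model2"} or \code{"model3"}.
#' @return A \linkS4class{FeatureTable}.
#' @export
extractFeatures <- function(rec, windows, modelTag) {
  if (!nrow(windows)) stop("argument error: no windows", call. = FALSE)
  lens <- windows$end_index - windows$start_index
  if (length(unique(lens)) != 1)
    stop("shape error: windows must have uniform length", call. = FALSE)
  L <- lens[1]
  if (!all(c("am", "gm") %in% names(rec@data))) rec <- attachMagnitudes(rec)
  fs <- rec@fs
  idx <- outer(windows$start_index, seq_len(L), `+`)   # 1-based sample index
  blocks <- lapply(FEATURE_CHANNELS, function(ch) {
    M <- matrix(rec@data[[ch]][idx], nrow = nrow(windows))
    B <- .batch_channel_features(M, fs)
    colnames(B) <- paste(ch, colnames(B), sep = "_")
    B
  })
  fm <- do.call(cbind, blocks)
  meta_cols <- intersect(c("calf_id", "start_index", "end_index", "start_s",
                           "peak_index", "peak_value", "action_label",
                           "state_label", "label"), names(windows))
  featureTable(cbind(windows[meta_cols], as.data.frame(fm)),
               featureNames = colnames(fm), modelTag = modelTag)
}

#' Drop highly correlated features
#'
#' Greedy single pass in fixed column order: a feature is dropped when its
#' absolute Pearson correlation with an already-kept feature reaches the
#' threshold; constant (zero-variance) columns are dropped outright, and a
#' correlation involving a zero-variance column is defined as 0. Every drop
#' is reported, so surviving and dropped features partition the original
#' set.
#'
#' @param ft a \linkS4class{FeatureTable} with >= 2 rows.
#' @param threshold absolute-correlation threshold in (0, 1].
#' @return list(table = filtered \linkS4class{FeatureTable},
#'   report = list(dropped_correlated, dropped_constant, surviving)).
#' @export
dropCorrelated <- function(ft, threshold = 0.9) {
  fm <- featureMatrix(ft)
  if (nrow(fm) < 2) stop("argument error: need >= 2 rows", call. = FALSE)
  sds <- apply(fm, 2, stats::sd)
  kept <- character()
  dropped <- data.frame(kept = character(), dropped = character(), r = numeric())
  constant <- character()
  for (f in colnames(fm)) {
    if (sds[f] == 0) { constant <- c(constant, f); next }
    r <- if (length(kept)) abs(stats::cor(fm[, f], fm[, kept, drop = FALSE])[1, ]) else numeric()
    r[is.na(r)] <- 0
    if (length(r) && max(r) >= threshold) {
      j <- which.max(r)
      dropped <- rbind(dropped, data.frame(kept = kept[j], dropped = f,
                                           r = unname(r[j])))
    } else kept <- c(kept, f)
  }
  meta <- setdiff(names(ft@data), ft@featureNames)
  list(table = featureTable(ft@data[c(meta, kept)], kept, ft@modelTag),
       report = list(dropped_correlated = dropped, dropped_constant = constant,
                     surviving = kept))
}

#' Select features by decision-tree importance
#'
#' Fits a single classification tree (seeded) of the labels on the features
#' and ranks features by its impurity-based importance. Either the top
#' \code{topK} features are kept, or features whose importance falls below
#' \code{minImportance} (default: exact zeros, i.e. features the tree never
#' uses) are dropped. Selection never increases the feature count; the
#' report carries the full ranking.
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param labelCol name of the label column in the table.
#' @param minImportance drop features with importance below this value.
#' @param topK keep exactly this many top-ranked features (overrides
#'   \code{minImportance}).
#' @param seed integer seed.
#' @return list(table = filtered \linkS4class{FeatureTable},
#'   report = list(importance, dropped_low_importance, surviving)).
#' @export
selectByImportance <- function(ft, labelCol, minImportance = NULL,
                               topK = NULL, seed = 1) {
  y <- factor(ft@data[[labelCol]])
  if (nlevels(y) < 2)
    stop("argument error: labels must contain at least 2 classes", call. = FALSE)
  fm <- as.data.frame(featureMatrix(ft))
  if (!is.null(topK) && topK > ncol(fm))
    stop("argument error: topK exceeds the number of features", call. = FALSE)
  set.seed(seed)
  fit <- rpart::rpart(y ~ ., data = cbind(y = y, fm), method = "class",
                      control = rpart::rpart.control(cp = 0.001, xval = 0))
  imp <- setNames(numeric(ncol(fm)), colnames(fm))
  vi <- fit$variable.importance
  imp[names(vi)] <- vi
  if (!is.null(topK)) {
    ord <- order(-imp, seq_along(imp))
    keep <- names(imp)[sort(ord[seq_len(topK)])]
  } else if (is.null(minImportance)) {
    keep <- names(imp)[imp > 0]      # drop exact zeros
  } else {
    keep <- names(imp)[imp >= minImportance]
  }
  dropped <- setdiff(names(imp), keep)
  meta <- setdiff(names(ft@data), ft@featureNames)
  list(table = featureTable(ft@data[c(meta, keep)], keep, ft@modelTag),
       report = list(importance = sort(imp, decreasing = TRUE),
                     dropped_low_importance = imp[dropped],
                     surviving = keep))
}
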