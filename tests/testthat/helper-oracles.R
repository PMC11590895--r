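# Independent oracles and small fixture builders used across test files.
# Oracles are deliberately naive (O(N^2) sums, exhaustive enumeration) and
# share no code with the implementation paths they check.

# recording with given channel series (defaults: stationary, lying flat on z)
make_recording <- function(n, fs = 25, calf = "c1",
                           ax = 0, ay = 0, az = 1,
                           gx = 0, gy = 0, gz = 0) {
  d <- data.frame(t = (seq_len(n) - 1) / fs,
                  ax = rep_len(ax, n), ay = rep_len(ay, n),
                  az = rep_len(az, n), gx = rep_len(gx, n),
                  gy = rep_len(gy, n), gz = rep_len(gz, n))
  imuRecording(calf, d, fs = fs)
}

# naive O(N^2) DFT: X[k] = sum_n x[n] exp(-i 2 pi k n / N)
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

# dominant frequency via the naive DFT, same conventions as the implementation
naive_dominant_frequency <- function(x, fs) {
  xc <- x - mean(x)
  X <- naive_dft(xc)
  kmax <- floor(length(x) / 2)
  pw <- Mod(X[2:(kmax + 1)])^2
  if (max(pw) <= length(x) * 1e-24) return(c(freq = 0, power = 0))
  k <- which.max(pw)
  c(freq = k * fs / length(x), power = pw[k])
}

# peak oracle: enumerate local maxima above threshold, then enforce spacing
# greedily by descending value with an explicit masking loop
oracle_peaks <- function(am, threshold, minsep) {
  n <- length(am)
  cand <- which(c(FALSE, am[2:(n - 1)] > am[1:(n - 2)] &
                    am[2:(n - 1)] >= am[3:n], FALSE) & am >= threshold)
  kept <- integer()
  pool <- cand
  while (length(pool)) {
    best <- pool[order(-am[pool], pool)[1]]
    kept <- c(kept, best)
    pool <- pool[abs(pool - best) >= minsep]
  }
  sort(kept) - 1L  # 0-based
}

# AUC oracle: fraction of concordant positive/negative score pairs, ties 1/2
oracle_auc <- function(actual, scores, positive) {
  sp <- scores[actual == positive]
  sn <- scores[actual != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# quantile oracle: type-7 linear interpolation written out by hand
oracle_iqr <- function(x) {
  s <- sort(x); n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q(0.75) - q(0.25)
}

# small labelled feature table for classifier tests: two gaussian blobs
# (plus distractor noise feature), labels by blob
make_blob_table <- function(n_per = 40, n_calves = 4, tag = "model2",
                            sep = 4, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per
  lab <- rep(c("lying", "standing"), each = n_per)
  d <- data.frame(
    calf_id = sample(sprintf("c%d", seq_len(n_calves)), n, TRUE),
    start_s = seq_len(n),
    state_label = lab,
    f1 = rnorm(n, ifelse(lab == "lying", 0, sep)),
    f2 = rnorm(n, ifelse(lab == "lying", 0, sep)),
    f3 = rnorm(n))
  calfIMU:::featureTable(d, c("f1", "f2", "f3"), tag)
}
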