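# Shared fixtures and independent oracles used across the suite.

# Short synthetic session: full channel set, a few seconds per condition.
tinySpec <- function(seconds = 10, nSubjects = 1L, seed = 42L, ...) {
  syntheticSpec(nSubjects = nSubjects,
                schedule = data.frame(
                  condition = c("baseline", "stress", "amusement"),
                  seconds = seconds),
                seed = seed, ...)
}

tinyRecord <- function(seconds = 10, seed = 42L, ...) {
  generateSubject(tinySpec(seconds = seconds, seed = seed, ...), 1L)
}

# Brute-force count of valid sliding-window positions.
bruteOutLen <- function(len, kernel, stride) {
  n <- 0L
  start <- 1L
  while (start + kernel - 1L <= len) {
    n <- n + 1L
    start <- start + stride
  }
  n
}

# Independent metric computation straight from prediction lists.
bruteMetrics <- function(truth, pred, classes) {
  acc <- mean(truth == pred)
  per <- t(vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }, numeric(3)))
  list(accuracy = acc, perClass = per,
       macroF1 = mean(per[, "f1"]),
       macroPrecision = mean(per[, "precision"]),
       macroRecall = mean(per[, "recall"]))
}

# Count local maxima above a threshold in a noiseless periodic signal.
countPeaks <- function(v, thresh = 0.5) {
  up <- v > thresh
  sum(diff(c(FALSE, up)) == 1L)
}

# Minimal hand-rolled window slicer for cross-checking segmentRecord.
bruteWindowCount <- function(nSamples, rate, windowS, strideS) {
  n <- 0L
  t <- 0
  repeat {
    if (round(rate * t) + round(rate * windowS) > nSamples) break
    n <- n + 1L
    t <- t + strideS
  }
  n
}
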