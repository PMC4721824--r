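# Independent brute-force oracles. Each reimplements a pipeline formula the
# slow, literal way (explicit loops, O(N^2) transforms) so the fast package
# implementations can be checked against a separate code path.

oracle_moving_average <- function(x, window) {
  h <- window %/% 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

oracle_entropy <- function(s) {
  m <- abs(s)
  if (max(m) == 0) return(0)
  w <- m / max(m)
  p <- w / sum(w)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

oracle_energy <- function(s) {
  tot <- 0
  for (v in s) tot <- tot + abs(v)^2
  tot
}

oracle_rms <- function(s) sqrt(sum(s^2) / length(s))

# O(N^2) DFT magnitude maximum, DC bin excluded.
oracle_amplitude <- function(s) {
  n <- length(s)
  mags <- numeric(n - 1)
  for (k in seq_len(n - 1)) {          # k = 1 .. n-1 (skip k = 0)
    re <- im <- 0
    for (j in seq_len(n)) {
      ang <- -2 * pi * k * (j - 1) / n
      re <- re + s[j] * cos(ang)
      im <- im + s[j] * sin(ang)
    }
    mags[k] <- sqrt(re^2 + im^2)
  }
  max(mags)
}

# Exhaustive extrema scan under the same prominence/distance rules as the
# package, written independently: full-vector scans for prominence, and
# iterative winner-takes-neighbourhood selection.
oracle_prominence <- function(x, i) {
  n <- length(x)
  higher_left <- which(x[seq_len(i - 1)] > x[i])
  lo <- if (length(higher_left) > 0) max(higher_left) + 1 else 1
  left_min <- min(x[lo:i])
  higher_right <- which(x[seq(i + 1, n)] > x[i]) + i
  hi <- if (i == n) n else if (length(higher_right) > 0) min(higher_right) - 1 else n
  right_min <- min(x[i:hi])
  x[i] - max(left_min, right_min)
}

oracle_peaks <- function(x, delta_d, delta_h) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  for (i in 2:(n - 1)) if (x[i] > x[i - 1] && x[i] > x[i + 1]) cand <- c(cand, i)
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) oracle_prominence(x, i), numeric(1))
  ok <- prom >= delta_h
  cand <- cand[ok]; prom <- prom[ok]
  kept <- integer(0)
  while (length(cand) > 0) {
    best <- which(prom == max(prom))
    best <- best[which.min(cand[best])]    # tie -> earliest index
    kept <- c(kept, cand[best])
    far <- abs(cand - cand[best]) >= delta_d
    cand <- cand[far]; prom <- prom[far]
  }
  sort(kept)
}

oracle_extrema <- function(x, delta_d, delta_h)
  list(peaks = oracle_peaks(x, delta_d, delta_h),
       valleys = oracle_peaks(-x, delta_d, delta_h))

# Per-cell one-vs-rest metric computation from a confusion matrix.
oracle_metrics <- function(m) {
  total <- sum(m)
  k <- nrow(m)
  correct <- 0
  for (i in seq_len(k)) correct <- correct + m[i, i]
  sens <- spec <- ppv <- numeric(k)
  for (c in seq_len(k)) {
    tp <- m[c, c]
    fn <- 0; for (j in seq_len(k)) if (j != c) fn <- fn + m[c, j]
    fp <- 0; for (i in seq_len(k)) if (i != c) fp <- fp + m[i, c]
    tn <- total - tp - fn - fp
    sens[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
    ppv[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  list(classification_rate = correct / total, sensitivity = mean(sens),
       specificity = mean(spec), ppv_per_class = ppv, avg_ppv = mean(ppv))
}

# Naive per-formula reimplementation of the whole feature vector.
oracle_features <- function(samples, sampling_rate) {
  n <- length(samples$Ax)
  out <- c(step_length = n, step_duration = n / sampling_rate)
  for (ch in names(samples)) {
    s <- samples[[ch]]
    mu <- sum(s) / n
    out[paste0(ch, "_mean")] <- mu
    out[paste0(ch, "_sd")] <- sqrt(sum((s - mu)^2) / (n - 1))
    out[paste0(ch, "_min")] <- min(s)
    out[paste0(ch, "_max")] <- max(s)
    out[paste0(ch, "_rms")] <- oracle_rms(s)
    out[paste0(ch, "_entropy")] <- oracle_entropy(s)
    out[paste0(ch, "_energy")] <- oracle_energy(s)
    out[paste0(ch, "_amplitude")] <- oracle_amplitude(s)
  }
  out
}
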