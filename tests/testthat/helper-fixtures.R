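# Shared fixture builders. Everything is generated in code at test time.

# A recording whose gaze is the target delayed by exactly `delay` samples,
# plus optional white noise: the latency estimator's constructed oracle.
pure_delay_recording <- function(n_targets = 8, delay = 237, noise_sd = 0,
                                 seed = 1) {
  seq1 <- generate_target_sequence(n_targets, seed = seed)
  tx <- rep(seq1$positions[, 1], each = 1000)
  ty <- rep(seq1$positions[, 2], each = 1000)
  n <- length(tx)
  gx <- c(rep(tx[1], delay), tx[1:(n - delay)])
  gy <- c(rep(ty[1], delay), ty[1:(n - delay)])
  if (noise_sd > 0) {
    set.seed(seed + 10000)
    gx <- gx + rnorm(n, 0, noise_sd)
    gy <- gy + rnorm(n, 0, noise_sd)
  }
  gaze_recording(time = seq_len(n) - 1, gx = gx, gy = gy, tx = tx, ty = ty)
}

# Brute-force excess mass for m = 1, 2 intervals with endpoints at data
# points, by full enumeration (oracle for small n).
brute_excess_mass <- function(xs, lambda) {
  xs <- sort(xs)
  n <- length(xs)
  score <- function(i, j) (j - i + 1) / n - lambda * (xs[j] - xs[i])
  e1 <- -Inf
  best_pair <- -Inf
  for (i in 1:n) for (j in i:n) {
    s1 <- score(i, j)
    if (s1 > e1) e1 <- s1
    if (j < n) {
      for (i2 in (j + 1):n) for (j2 in i2:n) {
        s <- s1 + score(i2, j2)
        if (s > best_pair) best_pair <- s
      }
    }
  }
  c(e1 = e1, e2 = max(e1, best_pair))
}

# Brute-force analysis-window selection (oracle for select_analysis_window).
brute_window <- function(curve, width) {
  n <- length(curve)
  means <- vapply(1:(n - width + 1),
                  function(s) mean(curve[s:(s + width - 1)]), 0)
  s <- which.min(means)
  c(start = s, end = s + width - 1)
}
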