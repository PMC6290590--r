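# Independent reference implementations used to verify the package's
# computational kernels. These deliberately avoid the package's own code
# paths (pure R, naive algorithms).

# Memoized recursive DTW with a Sakoe-Chiba band, |a-b| local cost,
# match/insert/delete steps, unnormalized.
dtw_oracle_recursive <- function(a, b, band) {
  n <- length(a)
  m <- length(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (abs(i - j) > band) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- abs(a[i] - b[j])
    val <- if (i == 1 && j == 1) cost
    else cost + min(if (i > 1) rec(i - 1, j) else Inf,
                    if (j > 1) rec(i, j - 1) else Inf,
                    if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf)
    memo[[key]] <- val
    val
  }
  rec(n, m)
}

# Iterative R dynamic program (for longer sequences where recursion is
# slow); same definition as above.
dtw_oracle_dp <- function(a, b, band) {
  n <- length(a)
  m <- length(b)
  D <- matrix(Inf, n, m)
  for (i in 1:n) {
    for (j in max(1, i - band):min(m, i + band)) {
      cost <- abs(a[i] - b[j])
      D[i, j] <- cost + if (i == 1 && j == 1) 0
      else min(if (i > 1) D[i - 1, j] else Inf,
               if (j > 1) D[i, j - 1] else Inf,
               if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
    }
  }
  D[n, m]
}

# Exhaustive double-loop distance scores: D(j) = min DTW over successors
# whose start time is at least start[j] + k seconds.
distance_scores_oracle <- function(X, start, k, band) {
  m <- nrow(X)
  vapply(seq_len(m), function(j) {
    best <- Inf
    for (j2 in seq_len(m)) {
      if (start[j2] < start[j] + k) next
      best <- min(best, dtw_oracle_dp(X[j, ], X[j2, ], band))
    }
    best
  }, numeric(1))
}

# Squared magnitude response of the package's default low-pass (4th-order
# Butterworth applied forward-backward) at frequency f, computed from the
# filter coefficients directly.
butter_filtfilt_gain <- function(f, cutoff, fs) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  H <- sum(bf$b * z^(-(seq_along(bf$b) - 1))) /
    sum(bf$a * z^(-(seq_along(bf$a) - 1)))
  Mod(H)^2  # filtfilt applies the filter twice
}

# Amplitude of a sinusoid of known frequency in a series (least squares).
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  co <- coef(lm(x ~ X - 1))
  sqrt(sum(co^2))
}
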