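# Small fixtures built in code, shared across test files.

# uniform recording from a raw anteroposterior vector
rec_from_signal <- function(z, fs = 100) {
  n <- length(z)
  accel_recording(data.frame(t = seq(0, by = 1 / fs, length.out = n),
                             ax = 0, ay = 0, az = z))
}

# pure tone recording
tone_rec <- function(freq, amp = 1, duration = 5, fs = 100, phase = 0) {
  t <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  rec_from_signal(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

# brute-force local-maximum scan: independent oracle for peak counting
brute_local_maxima <- function(x) {
  which(diff(sign(diff(x))) < 0) + 1L
}

# independent Passing-Bablok oracle by direct enumeration
brute_passing_bablok <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- c(s, if (dx == 0) sign(dy) * Inf else dy / dx)
    }
  }
  s <- sort(s[s != -1])
  k <- sum(s < -1)
  nn <- length(s)
  b <- if (nn %% 2 == 1) s[(nn + 1) / 2 + k] else {
    (s[nn / 2 + k] + s[nn / 2 + 1 + k]) / 2
  }
  list(slope = b, intercept = median(y - b * x))
}

# independent CCC oracle via direct moment formulas
brute_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# independent percentile-based MdAPE oracle
brute_mdape <- function(x, y) {
  ape <- 100 * abs(y - x) / abs(x)
  sort_ape <- sort(ape)
  n <- length(ape)
  h <- (n - 1) * 0.5 + 1
  lo <- floor(h)
  sort_ape[lo] + (h - lo) * (sort_ape[min(lo + 1, n)] - sort_ape[lo])
}
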