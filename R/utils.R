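# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive n child seeds from one master seed (keeps all values < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# DFT bin frequencies, matching numpy.fft.fftfreq ordering.
fft_freqs <- function(n, d = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

fft_shift <- function(x) {
  n <- length(x)
  x[c(seq.int(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))]
}

# Truncated normal draw by rejection (vectors allowed; bounds recycled).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) abort("standard deviation must be non-negative")
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)[seq_along(bad)]
    bad <- which(x < lower | x > upper)
    guard <- guard + 1L
  }
  pmin(pmax(x, lower), upper)
}

# Weighted moments of a discrete distribution: values x with probabilities p.
dist_moments <- function(x, p) {
  p <- p / sum(p)
  m <- sum(p * x)
  v <- sum(p * (x - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) sum(p * (x - m)^3) / s^3 else 0
  kurt <- if (s > 0) sum(p * (x - m)^4) / s^4 else 0
  list(mean = m, sd = s, skew = skew, kurtosis = kurt)
}

# Shannon entropy of a probability vector, normalized to [0, 1] by log(n).
norm_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

# Quantiles of a distribution over an ordered axis (linear interpolation on
# the cumulative mass).
dist_quantile <- function(x, p, probs) {
  p <- p / sum(p)
  cm <- cumsum(p)
  vapply(probs, function(q) {
    i <- which(cm >= q)[1]
    if (is.na(i)) return(x[length(x)])
    if (i == 1L) return(x[1])
    # interpolate between bin i-1 and i
    x[i - 1] + (x[i] - x[i - 1]) * (q - cm[i - 1]) / (cm[i] - cm[i - 1])
  }, numeric(1))
}

# FFT-based zero-phase low-pass filter with a raised-cosine transition band.
# The input is zero-padded to a highly composite length so the transform stays
# O(n log n) for arbitrary input sizes.
fft_lowpass <- function(x, fs, cutoff, transition = cutoff * 0.2) {
  n0 <- length(x)
  n <- stats::nextn(n0)
  xp <- c(x, numeric(n - n0))
  f <- abs(fft_freqs(n, d = 1 / fs))
  gain <- rep(1, n)
  ramp <- f > cutoff & f < cutoff + transition
  gain[f >= cutoff + transition] <- 0
  gain[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - cutoff) / transition))
  (Re(fft(fft(xp) * gain, inverse = TRUE)) / n)[seq_len(n0)]
}

# Zero-phase FFT filter with an arbitrary magnitude response gain_fun(f).
fft_shape <- function(x, fs, gain_fun) {
  n0 <- length(x)
  n <- stats::nextn(n0)
  xp <- c(x, numeric(n - n0))
  gain <- gain_fun(abs(fft_freqs(n, d = 1 / fs)))
  (Re(fft(fft(xp) * gain, inverse = TRUE)) / n)[seq_len(n0)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
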