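# Internal numerical helpers shared across modules.

# Mass-conserving Gaussian smoothing on a uniform grid. Each source bin
# redistributes its mass over a truncated (+/-4 SD) Gaussian kernel; near the
# edges the kernel is renormalized to its in-range mass, so the total is
# conserved exactly. sdBins = 0 is the identity.
.gaussSmooth <- function(x, sdBins) {
  n <- length(x)
  if (sdBins <= 0 || n < 2L) return(x)
  h <- max(1L, ceiling(4 * sdBins))
  off <- seq.int(-h, h)
  k <- exp(-off^2 / (2 * sdBins^2))
  k <- k / sum(k)
  norm <- rep(0, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    keep <- i + off[j] >= 1L & i + off[j] <= n
    norm[keep] <- norm[keep] + k[j]
  }
  y <- rep(0, n)
  for (j in seq_along(off)) {
    i <- which(seq_len(n) + off[j] >= 1L & seq_len(n) + off[j] <= n)
    if (length(i)) y[i + off[j]] <- y[i + off[j]] + x[i] * k[j] / norm[i]
  }
  y
}

# Row-wise version of .gaussSmooth for a matrix of surrogate correlograms.
.gaussSmoothRows <- function(m, sdBins) {
  n <- ncol(m)
  if (sdBins <= 0 || n < 2L) return(m)
  h <- max(1L, ceiling(4 * sdBins))
  off <- seq.int(-h, h)
  k <- exp(-off^2 / (2 * sdBins^2))
  k <- k / sum(k)
  norm <- rep(0, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    keep <- i + off[j] >= 1L & i + off[j] <= n
    norm[keep] <- norm[keep] + k[j]
  }
  y <- matrix(0, nrow(m), n)
  for (j in seq_along(off)) {
    i <- which(seq_len(n) + off[j] >= 1L & seq_len(n) + off[j] <= n)
    if (length(i))
      y[, i + off[j]] <- y[, i + off[j]] +
        sweep(m[, i, drop = FALSE], 2, k[j + 0L] / norm[i], "*")
  }
  y
}

# Number of elements of the sorted vector `times` strictly below x
# (vectorized over x). Used to count spikes in half-open windows [a, b).
.nBefore <- function(x, times) {
  if (!length(times)) return(rep(0L, length(x)))
  findInterval(x, times, left.open = TRUE)
}

# Spike counts in the half-open window [event + win[1], event + win[2])
# for each event. `times` must be sorted.
.eventCounts <- function(times, events, win) {
  .nBefore(events + win[2], times) - .nBefore(events + win[1], times)
}

# Draw a homogeneous Poisson process on [t0, t1) at `rate` Hz.
.homPoisson <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# Force strict monotonicity by dropping exact duplicates (measure-zero for
# continuous draws, but guards assembled trains).
.strictSort <- function(x) {
  x <- sort(x)
  if (length(x) > 1L) x <- x[c(TRUE, diff(x) > 0)]
  x
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
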