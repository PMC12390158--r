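# Independent brute-force oracles used to check the package's
# implementations.  These deliberately take different computational routes
# (stats::aov, exhaustive scans, closed forms) from the code under test.

# Two-way ANOVA ICC(A,k) by fitting the crossed model with stats::aov and
# reading mean squares off the ANOVA table.
oracle_icc_a_k <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ row + col, data = d))[[1]]
  MSR <- tab["row", "Mean Sq"]
  MSC <- tab["col", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (MSC - MSE) / n)
}

# Cross-correlation lag by exhaustive scan with stats::cor on overlapping
# segments (positive lag: b starts later than a).
oracle_lag <- function(a, b, max_lag) {
  best <- NA; best_r <- -Inf
  for (l in -max_lag:max_lag) {
    if (l >= 0) {
      m <- min(length(a) - l, length(b))
      r <- stats::cor(a[(1 + l):(l + m)], b[1:m])
    } else {
      m <- min(length(a), length(b) + l)
      r <- stats::cor(a[1:m], b[(1 - l):(m - l)])
    }
    if (is.finite(r) && r > best_r) { best_r <- r; best <- -l }
  }
  best
}

# Maximal below-threshold runs of at least min_len samples, by plain loop.
oracle_runs <- function(x, thresh, min_len) {
  out <- list(); start <- NA
  for (i in seq_along(x)) {
    if (x[i] < thresh) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      if (i - start >= min_len) out[[length(out) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start) && length(x) - start + 1 >= min_len)
    out[[length(out) + 1]] <- c(start, length(x))
  out
}

# Brute-force scan for windows of >= min_bursts events spanning <= span_s.
oracle_sessions <- function(times, min_bursts, span_s) {
  member <- rep(FALSE, length(times))
  for (i in seq_along(times)) for (j in seq_along(times)) {
    if (j - i + 1 >= min_bursts && times[j] - times[i] <= span_s)
      member[i:j] <- TRUE
  }
  member
}

# Jaccard overlap of two [start, end] intervals.
jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# A short noise-free still stream in a tilted orientation.
make_still_stream <- function(n = 200, q = c(1, 0, 0, 0), rate = 20,
                              noise = 0) {
  ef <- spinewear:::earth_field_vector(1, -60)
  acc <- spinewear:::quat_rotate_inv_rows(matrix(q, n, 4, byrow = TRUE),
                                          c(0, 0, 1))
  mag <- spinewear:::quat_rotate_inv_rows(matrix(q, n, 4, byrow = TRUE), ef)
  if (noise > 0) {
    acc <- acc + matrix(stats::rnorm(3 * n, 0, noise), n, 3)
    mag <- mag + matrix(stats::rnorm(3 * n, 0, noise), n, 3)
  }
  sensor_stream("still", (seq_len(n) - 1) / rate, acc,
                matrix(0, n, 3), mag, rate = rate)
}
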