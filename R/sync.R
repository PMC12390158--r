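# Inter-sensor synchronization: cross-correlation lag estimation at hourly
# checkpoints, a linear clock-drift model per sensor, and resampling onto
# the reference sensor's clock grid.

# Orientation-invariant correlation signal: |acc| - 1 g.
accel_magnitude_signal <- function(stream) {
  sqrt(rowSums(stream$acc^2)) - 1
}

#' Estimate the integer lag between two signals by cross-correlation
#'
#' Both series are mean-removed; the normalized cross-correlation is scanned
#' over integer lags in `[-max_lag, max_lag]`.  A positive lag means `b`
#' starts later than `a` (i.e. `b[i] ~ a[i - lag]`).
#'
#' @param a,b Numeric vectors (e.g. acceleration magnitude) on a common
#'   nominal grid.
#' @param max_lag Maximum lag to scan, in samples.
#' @param min_peak Minimum normalized correlation peak; below it the lag is
#'   considered undefined (quiet/uninformative windows).
#' @return Integer lag with attribute `peak` (normalized peak correlation).
#' @export
estimate_lag <- function(a, b, max_lag, min_peak = 0.5) {
  a <- a - mean(a); b <- b - mean(b)
  na <- length(a); nb <- length(b)
  if (min(na, nb) < 2 * max_lag)
    stop("series must be at least 2 * max_lag long")
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0)
    stop("undefined lag: constant input")
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      m <- min(na - l, nb)
      if (m < 2) return(0)
      sum(a[(1 + l):(l + m)] * b[1:m])
    } else {
      m <- min(na, nb + l)
      if (m < 2) return(0)
      sum(a[1:m] * b[(1 - l):(m - l)])
    }
  }, numeric(1)) / (sa * sb)
  # b[i] = a[i - L]: correlation peaks where a is advanced by L
  i <- which.max(cc)
  peak <- cc[i]
  if (peak < min_peak)
    stop(sprintf("undefined lag: correlation peak %.2f below %.2f",
                 peak, min_peak))
  structure(-lags[i], peak = peak)
}

#' Estimate per-sensor clock drift against a reference sensor
#'
#' At checkpoints spaced `checkpoint_interval_s` apart, the lag between each
#' sensor and the reference is measured by cross-correlating the
#' acceleration-magnitude signal over a `window_s` window; a least-squares
#' line (lag vs. time) gives the relative clock-speed error (slope,
#' samples/s) and initial offset (intercept, samples).  Because accumulated
#' drift can exceed the scan range, each checkpoint's search is centered on
#' the previous checkpoint's lag.
#'
#' @param streams Named list of [sensor_stream()]s on the same nominal rate.
#' @param reference Name (or id) of the reference sensor; default the first.
#' @param checkpoint_interval_s Checkpoint spacing (s); default hourly.
#' @param window_s Correlation window length (s).
#' @param max_lag_s Half-width of the lag scan around the tracked lag (s).
#' @param min_peak Correlation-peak quality gate; checkpoints below it are
#'   discarded.
#' @return An object of class `drift_model`: per-sensor checkpoints
#'   (time_s, lag_samples, peak) and fitted `slope` / `intercept`.
#' @export
estimate_clock_drift <- function(streams, reference = names(streams)[1],
                                 checkpoint_interval_s = 3600,
                                 window_s = 60, max_lag_s = 10,
                                 min_peak = 0.5) {
  ref <- streams[[reference]]
  if (is.null(ref)) stop("reference sensor not found: ", reference)
  rate <- ref$rate
  duration <- max(ref$time) - min(ref$time)
  if (duration < 2 * checkpoint_interval_s)
    stop("insufficient data: recording shorter than 2 checkpoint intervals")
  sig_ref <- accel_magnitude_signal(ref)
  max_lag <- round(max_lag_s * rate)
  nwin <- round(window_s * rate)
  # One checkpoint per interval, placed on the most informative (highest
  # variance) window of the interval: quiet stretches carry no sync signal.
  interval_starts <- seq(min(ref$time), max(ref$time) - window_s - max_lag_s,
                         by = checkpoint_interval_s)
  checkpoints <- vapply(interval_starts, function(t0) {
    cand <- seq(t0, min(t0 + checkpoint_interval_s - window_s,
                        max(ref$time) - window_s - max_lag_s),
                by = window_s / 2)
    v <- vapply(cand, function(ct) {
      i0 <- findInterval(ct, ref$time)
      i1 <- min(i0 + nwin - 1, length(sig_ref))
      stats::var(sig_ref[i0:i1])
    }, numeric(1))
    cand[which.max(v)]
  }, numeric(1))

  models <- list()
  for (nm in setdiff(names(streams), reference)) {
    st <- streams[[nm]]
    sig <- accel_magnitude_signal(st)
    lag_track <- 0
    rows <- list()
    for (ct in checkpoints) {
      i0 <- findInterval(ct, ref$time)
      ia <- i0:(i0 + nwin - 1)
      # shift the sensor window by the tracked lag so the residual stays
      # inside the scan range even when accumulated drift exceeds it
      j0 <- i0 + round(lag_track)
      jb <- j0:(j0 + nwin - 1)
      if (min(ia) < 1 || max(ia) > length(sig_ref) ||
          min(jb) < 1 || max(jb) > length(sig)) next
      res <- tryCatch(
        estimate_lag(sig_ref[ia], sig[jb], max_lag = max_lag,
                     min_peak = min_peak),
        error = function(e) NULL)
      if (is.null(res)) next
      lag <- as.numeric(res) + (j0 - i0)
      lag_track <- lag
      rows[[length(rows) + 1]] <- data.frame(
        time_s = ct, lag_samples = lag, peak = attr(res, "peak"))
    }
    cps <- if (length(rows)) do.call(rbind, rows) else
      data.frame(time_s = numeric(0), lag_samples = numeric(0),
                 peak = numeric(0))
    if (nrow(cps) < 2)
      stop("insufficient data: fewer than 2 valid checkpoints for ", nm)
    fit <- stats::lm(lag_samples ~ time_s, data = cps)
    models[[nm]] <- list(checkpoints = cps,
                         slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]))
  }
  structure(list(reference = reference, rate = rate, sensors = models,
                 checkpoint_interval_s = checkpoint_interval_s,
                 window_s = window_s),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> reference '%s', %d sensor(s)\n", x$reference,
              length(x$sensors)))
  for (nm in names(x$sensors))
    cat(sprintf("  %s: slope %.3g samples/s, intercept %.2f samples (%d checkpoints)\n",
                nm, x$sensors[[nm]]$slope, x$sensors[[nm]]$intercept,
                nrow(x$sensors[[nm]]$checkpoints)))
  invisible(x)
}

#' Serialize a drift model to JSON for audit
#' @param model A `drift_model`. @param path Output path.
#' @export
write_drift_model <- function(model, path) {
  jsonlite::write_json(list(
    reference = model$reference, rate = model$rate,
    sensors = lapply(model$sensors, function(s)
      list(slope = s$slope, intercept = s$intercept,
           checkpoints = s$checkpoints))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Resample a sensor stream onto the reference clock
#'
#' The fitted lag line `lag(t) = slope * t + intercept` (samples) maps
#' reference time to the sensor's own timeline; all channels are linearly
#' interpolated there, yielding a stream aligned with the reference grid.
#'
#' @param stream A [sensor_stream()].
#' @param model A `drift_model` from [estimate_clock_drift()], or `NULL`
#'   for the reference sensor (identity).
#' @param ref_time Optional reference time grid; defaults to the stream's
#'   own claimed timestamps.
#' @return A corrected [sensor_stream()] on the reference grid.
#' @export
resynchronize <- function(stream, model = NULL, ref_time = stream$time) {
  slope <- 0; intercept <- 0
  if (!is.null(model)) {
    if (stream$sensor_id %in% names(model$sensors)) {
      m <- model$sensors[[stream$sensor_id]]
      slope <- m$slope; intercept <- m$intercept
    } else if (stream$sensor_id != model$reference) {
      stop("drift model does not cover sensor ", stream$sensor_id)
    }
  }
  # sensor-claimed time at which the event of reference time t was recorded
  tau <- ref_time + (slope * ref_time + intercept) / stream$rate
  tau <- pmin(max(stream$time), pmax(min(stream$time), tau))
  interp <- function(m) vapply(seq_len(ncol(m)), function(j)
    stats::approx(stream$time, m[, j], xout = tau, rule = 2)$y,
    numeric(length(tau)))
  sensor_stream(stream$sensor_id, ref_time, interp(stream$acc),
                interp(stream$gyr), interp(stream$mag), rate = stream$rate)
}

#' Synchronize a set of streams onto the reference sensor's grid
#'
#' Convenience wrapper: estimates the drift model (falling back to a single
#' constant-lag alignment for recordings shorter than two checkpoints, as
#' with a calibration-board initial sync) and resamples every stream onto
#' the reference grid.
#'
#' @inheritParams estimate_clock_drift
#' @return List with `streams` (corrected, common grid) and `model`.
#' @export
synchronize_streams <- function(streams, reference = names(streams)[1],
                                checkpoint_interval_s = 3600,
                                window_s = 60, max_lag_s = 10,
                                min_peak = 0.5) {
  ref <- streams[[reference]]
  duration <- max(ref$time) - min(ref$time)
  model <- NULL
  if (duration >= 2 * checkpoint_interval_s) {
    model <- tryCatch(
      estimate_clock_drift(streams, reference, checkpoint_interval_s,
                           window_s, max_lag_s, min_peak),
      error = function(e) NULL)
  }
  if (is.null(model)) {
    # single-lag alignment over the densest shared window
    sensors <- list()
    sig_ref <- accel_magnitude_signal(ref)
    max_lag <- round(max_lag_s * ref$rate)
    for (nm in setdiff(names(streams), reference)) {
      sig <- accel_magnitude_signal(streams[[nm]])
      m <- min(length(sig_ref), length(sig))
      lag <- tryCatch(as.numeric(estimate_lag(sig_ref[1:m], sig[1:m],
                                              max_lag = max_lag,
                                              min_peak = min_peak)),
                      error = function(e) 0)
      sensors[[nm]] <- list(
        checkpoints = data.frame(time_s = 0, lag_samples = lag, peak = NA),
        slope = 0, intercept = lag)
    }
    model <- structure(list(reference = reference, rate = ref$rate,
                            sensors = sensors,
                            checkpoint_interval_s = checkpoint_interval_s,
                            window_s = window_s),
                       class = "drift_model")
  }
  out <- lapply(names(streams), function(nm) {
    if (nm == reference) streams[[nm]]
    else resynchronize(streams[[nm]], model, ref_time = ref$time)
  })
  names(out) <- names(streams)
  list(streams = out, model = model)
}
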