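# Gyroscope bias: stillness detection, piecewise-linear bias model, removal.

#' Detect stillness intervals from the gyroscope
#'
#' Maximal runs where the gyroscope magnitude stays below `gyro_thresh_dps`
#' for at least `min_duration_s`.  The accelerometer is deliberately not
#' consulted: stillness is defined on the gyroscope alone.
#'
#' @param stream A [sensor_stream()].
#' @param gyro_thresh_dps Gyro magnitude threshold (deg/s), must be > 0.
#' @param min_duration_s Minimum interval duration (s).
#' @param max_window_s Long stillness runs are subdivided into windows of
#'   at most roughly this length, so a slowly drifting bias gets one knot
#'   per window instead of a single average over hours (e.g. sleep).
#' @return An object of class `stillness_intervals`: data.frame with
#'   start_s, end_s, per-axis mean gyro (mean_x/y/z, deg/s), noise s.d.
#'   (sd_x/y/z) and n samples.  May have zero rows.
#' @export
detect_stillness <- function(stream, gyro_thresh_dps = 3, min_duration_s = 5,
                             max_window_s = 60) {
  if (gyro_thresh_dps <= 0) stop("gyro threshold must be > 0")
  gmag <- sqrt(rowSums(stream$gyr^2))
  still <- gmag < gyro_thresh_dps
  r <- rle(still)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  keep <- which(r$values)
  rows <- list()
  for (k in keep) {
    i0 <- starts_i[k]; i1 <- ends_i[k]
    dur <- stream$time[i1] - stream$time[i0]
    if (dur < min_duration_s) next
    n_chunks <- max(1L, floor(dur / max_window_s))
    bounds <- round(seq(i0, i1, length.out = n_chunks + 1))
    for (c_ in seq_len(n_chunks)) {
      j0 <- bounds[c_]; j1 <- bounds[c_ + 1]
      g <- stream$gyr[j0:j1, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        start_s = stream$time[j0], end_s = stream$time[j1],
        mean_x = mean(g[, 1]), mean_y = mean(g[, 2]), mean_z = mean(g[, 3]),
        sd_x = stats::sd(g[, 1]), sd_y = stats::sd(g[, 2]),
        sd_z = stats::sd(g[, 3]), n = nrow(g))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               mean_x = numeric(0), mean_y = numeric(0), mean_z = numeric(0),
               sd_x = numeric(0), sd_y = numeric(0), sd_z = numeric(0),
               n = integer(0))
  structure(out, class = c("stillness_intervals", "data.frame"))
}

#' Fit a piecewise-linear gyro-bias model
#'
#' One knot per stillness interval, placed at the interval midpoint with the
#' interval's per-axis mean gyro as value; evaluation interpolates linearly
#' between knots and extrapolates with the nearest knot's value.  A single
#' interval yields a constant model.
#'
#' @param intervals A [detect_stillness()] result with >= 1 interval.
#' @return An object of class `bias_model` with `knot_t` and `knots`
#'   (m x 3, deg/s).
#' @export
fit_bias_model <- function(intervals) {
  if (nrow(intervals) == 0)
    stop("no stillness intervals: cannot estimate gyro bias")
  knot_t <- (intervals$start_s + intervals$end_s) / 2
  ord <- order(knot_t)
  structure(list(knot_t = knot_t[ord],
                 knots = cbind(intervals$mean_x,
                               intervals$mean_y,
                               intervals$mean_z)[ord, , drop = FALSE]),
            class = "bias_model")
}

#' Evaluate a bias model at given times
#' @param model A `bias_model`. @param t Times (s).
#' @return n x 3 matrix of per-axis bias (deg/s).
#' @export
eval_bias_model <- function(model, t) {
  if (length(model$knot_t) == 1)
    return(matrix(model$knots, length(t), 3, byrow = TRUE))
  vapply(1:3, function(j)
    stats::approx(model$knot_t, model$knots[, j], xout = t, rule = 2)$y,
    numeric(length(t)))
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> %d knot(s), t in [%.1f, %.1f] s\n",
              length(x$knot_t), min(x$knot_t), max(x$knot_t)))
  invisible(x)
}

#' Subtract a fitted bias from the gyroscope channels
#'
#' @param stream A [sensor_stream()].
#' @param model A `bias_model`, or `NULL` for a zero-bias fallback (used
#'   with a warning when no stillness was found).
#' @return The stream with `gyr` replaced by `gyr - bias(t)`; all other
#'   channels untouched.
#' @export
remove_bias <- function(stream, model) {
  if (is.null(model)) {
    warning("no bias model: falling back to zero bias")
    return(stream)
  }
  stream$gyr <- stream$gyr - eval_bias_model(model, stream$time)
  stream
}

#' Estimate and remove gyro bias in one step
#' @inheritParams detect_stillness
#' @return List with the corrected `stream`, the `model` (or NULL) and the
#'   stillness `intervals`.
#' @export
correct_gyro_bias <- function(stream, gyro_thresh_dps = 3,
                              min_duration_s = 5) {
  intervals <- detect_stillness(stream, gyro_thresh_dps, min_duration_s)
  model <- if (nrow(intervals)) fit_bias_model(intervals) else NULL
  corrected <- if (is.null(model)) {
    warning("no stillness found for ", stream$sensor_id,
            ": gyro bias left uncorrected")
    stream
  } else remove_bias(stream, model)
  list(stream = corrected, model = model, intervals = intervals)
}
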