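# Core containers: raw sensor streams, orientation series, joint-angle series.

#' Construct a sensor stream
#'
#' A `sensor_stream` holds one IMU's synchronized tri-axial time series:
#' accelerometer in g, gyroscope in deg/s, and magnetometer in normalized
#' units (undisturbed Earth-field magnitude = 1).
#'
#' @param sensor_id Character scalar, e.g. `"t12l1"`, `"l5s1"`, `"thigh"`.
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param acc,gyr,mag Numeric n x 3 matrices (columns x, y, z).
#' @param rate Nominal sampling rate in Hz (default 20).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(sensor_id, time, acc, gyr, mag, rate = 20) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr); mag <- as.matrix(mag)
  n <- length(time)
  if (rate <= 0) stop("nominal rate must be > 0")
  if (ncol(acc) != 3 || ncol(gyr) != 3 || ncol(mag) != 3)
    stop("acc, gyr and mag must each have 3 columns")
  if (nrow(acc) != n || nrow(gyr) != n || nrow(mag) != n)
    stop("all channels must have the same length as time")
  if (n > 1 && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing")
  structure(
    list(sensor_id = as.character(sensor_id), rate = rate,
         time = as.numeric(time), acc = unname(acc), gyr = unname(gyr),
         mag = unname(mag)),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream '%s'> %d samples @ %g Hz, t = [%.2f, %.2f] s\n",
              x$sensor_id, length(x$time), x$rate,
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA))
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) length(x$time)

sensor_table_cols <- c("time_s", "ax_g", "ay_g", "az_g",
                       "gx_dps", "gy_dps", "gz_dps", "mx", "my", "mz")

#' Read a sensor stream from a delimited text table
#'
#' Expects the ten columns `time_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps,
#' mx, my, mz`.  Rows containing non-finite values are dropped with a warning.
#'
#' @param path Path to the delimited file (comma-separated).
#' @param sensor_id Sensor identity; defaults to the file name without
#'   extension.
#' @param rate Nominal sampling rate in Hz.
#' @return A [sensor_stream()].
#' @export
read_sensor_table <- function(path, sensor_id = NULL, rate = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(sensor_table_cols, names(dt))
  if (length(missing_cols))
    stop("sensor table format error, missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0) stop("empty sensor file: ", path)
  m <- as.matrix(dt[, sensor_table_cols, with = FALSE])
  ok <- rowSums(!is.finite(m)) == 0
  if (any(!ok))
    warning(sprintf("dropped %d rows with non-finite values from %s",
                    sum(!ok), path))
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) stop("no finite rows in sensor file: ", path)
  if (is.null(sensor_id)) sensor_id <- sub("\\.[^.]*$", "", basename(path))
  sensor_stream(sensor_id, m[, 1], m[, 2:4], m[, 5:7], m[, 8:10], rate = rate)
}

#' Write a sensor stream to a delimited text table
#' @param stream A [sensor_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(stream, path) {
  dt <- data.table::data.table(
    time_s = stream$time,
    ax_g = stream$acc[, 1], ay_g = stream$acc[, 2], az_g = stream$acc[, 3],
    gx_dps = stream$gyr[, 1], gy_dps = stream$gyr[, 2], gz_dps = stream$gyr[, 3],
    mx = stream$mag[, 1], my = stream$mag[, 2], mz = stream$mag[, 3])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Construct an orientation series
#'
#' @param time Timestamps in seconds.
#' @param quat n x 4 matrix of scalar-first unit quaternions (sensor to
#'   Earth).
#' @param gain Filter gain used to produce the series (for provenance).
#' @param rate Sampling rate in Hz.
#' @return An object of class `orientation_series`.
#' @export
orientation_series <- function(time, quat, gain = NA_real_, rate = 20) {
  quat <- as.matrix(quat)
  if (length(time) != nrow(quat)) stop("time and quat lengths differ")
  if (nrow(quat) && any(abs(sqrt(rowSums(quat^2)) - 1) > 1e-6))
    stop("quaternions must be unit norm")
  structure(list(time = as.numeric(time), quat = unname(quat),
                 gain = gain, rate = rate),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples @ %g Hz (gain = %s)\n",
              length(x$time), x$rate, format(x$gain)))
  invisible(x)
}

#' Construct a joint-angle series
#'
#' Lumbar joint Euler angles in degrees: lateral flexion (x), flexion-
#' extension (y, forward flexion positive), axial rotation (z).
#'
#' @param time Timestamps in seconds.
#' @param angles n x 3 numeric matrix with columns latflex, flexext, rot
#'   (degrees).
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(time, angles) {
  angles <- as.matrix(angles)
  if (length(time) != nrow(angles)) stop("time and angles lengths differ")
  if (ncol(angles) != 3) stop("angles must have 3 columns")
  if (nrow(angles) && any(!is.finite(angles))) stop("angles must be finite")
  colnames(angles) <- c("latflex", "flexext", "rot")
  structure(list(time = as.numeric(time), angles = angles),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d samples, flexext range [%.1f, %.1f] deg\n",
              length(x$time),
              if (length(x$time)) min(x$angles[, "flexext"]) else NA,
              if (length(x$time)) max(x$angles[, "flexext"]) else NA))
  invisible(x)
}

#' Write a joint-angle series as delimited text
#' @param joint A [joint_angle_series()].
#' @param path Output file path.
#' @export
write_joint_angles <- function(joint, path) {
  data.table::fwrite(data.table::data.table(
    time_s = joint$time,
    latflex_deg = joint$angles[, "latflex"],
    flexext_deg = joint$angles[, "flexext"],
    rot_deg = joint$angles[, "rot"]), path)
  invisible(path)
}
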