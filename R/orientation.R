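# Orientation estimation: gradient-descent (Madgwick-type) MARG
# complementary filter and lumbar joint angles from paired spine sensors.
#
# The filter integrates the gyroscope quaternion derivative and corrects it
# by descending the gravity + magnetic-field alignment objective, using the
# normalized accelerometer and magnetometer readings.  Earth frame: z up,
# x = horizontal projection of the magnetic field.

# One MARG update; scalar arithmetic inlined for speed (this runs per
# sample inside estimate_orientation).
marg_step <- function(q1, q2, q3, q4, ax, ay, az, gx, gy, gz, mx, my, mz,
                      beta, dt) {
  # gyro quaternion derivative (gx.. in rad/s)
  qDot1 <- 0.5 * (-q2 * gx - q3 * gy - q4 * gz)
  qDot2 <- 0.5 * (q1 * gx + q3 * gz - q4 * gy)
  qDot3 <- 0.5 * (q1 * gy - q2 * gz + q4 * gx)
  qDot4 <- 0.5 * (q1 * gz + q2 * gy - q3 * gx)

  anorm <- sqrt(ax * ax + ay * ay + az * az)
  mnorm <- sqrt(mx * mx + my * my + mz * mz)
  if (beta > 0 && anorm > 0 && mnorm > 0) {
    ax <- ax / anorm; ay <- ay / anorm; az <- az / anorm
    mx <- mx / mnorm; my <- my / mnorm; mz <- mz / mnorm

    # reference field direction in Earth frame from the current estimate
    hx <- mx * (1 - 2 * (q3 * q3 + q4 * q4)) +
      my * 2 * (q2 * q3 - q1 * q4) + mz * 2 * (q2 * q4 + q1 * q3)
    hy <- mx * 2 * (q2 * q3 + q1 * q4) +
      my * (1 - 2 * (q2 * q2 + q4 * q4)) + mz * 2 * (q3 * q4 - q1 * q2)
    hz <- mx * 2 * (q2 * q4 - q1 * q3) + my * 2 * (q3 * q4 + q1 * q2) +
      mz * (1 - 2 * (q2 * q2 + q3 * q3))
    bx <- sqrt(hx * hx + hy * hy)
    bz <- hz

    # objective: predicted gravity (Earth +z) and field (bx, 0, bz) in the
    # sensor frame minus the measurements
    f1 <- 2 * (q2 * q4 - q1 * q3) - ax
    f2 <- 2 * (q1 * q2 + q3 * q4) - ay
    f3 <- 1 - 2 * (q2 * q2 + q3 * q3) - az
    f4 <- bx * (1 - 2 * (q3 * q3 + q4 * q4)) + bz * 2 * (q2 * q4 - q1 * q3) - mx
    f5 <- bx * 2 * (q2 * q3 - q1 * q4) + bz * 2 * (q1 * q2 + q3 * q4) - my
    f6 <- bx * 2 * (q1 * q3 + q2 * q4) + bz * (1 - 2 * (q2 * q2 + q3 * q3)) - mz

    # gradient = J^T f
    s1 <- -2 * q3 * f1 + 2 * q2 * f2 +
      (-2 * bz * q3) * f4 + (-2 * bx * q4 + 2 * bz * q2) * f5 +
      (2 * bx * q3) * f6
    s2 <- 2 * q4 * f1 + 2 * q1 * f2 - 4 * q2 * f3 +
      (2 * bz * q4) * f4 + (2 * bx * q3 + 2 * bz * q1) * f5 +
      (2 * bx * q4 - 4 * bz * q2) * f6
    s3 <- -2 * q1 * f1 + 2 * q4 * f2 - 4 * q3 * f3 +
      (-4 * bx * q3 - 2 * bz * q1) * f4 + (2 * bx * q2 + 2 * bz * q4) * f5 +
      (2 * bx * q1 - 4 * bz * q3) * f6
    s4 <- 2 * q2 * f1 + 2 * q3 * f2 +
      (-4 * bx * q4 + 2 * bz * q2) * f4 + (-2 * bx * q1 + 2 * bz * q3) * f5 +
      (2 * bx * q2) * f6
    snorm <- sqrt(s1 * s1 + s2 * s2 + s3 * s3 + s4 * s4)
    if (snorm > 0) {
      qDot1 <- qDot1 - beta * s1 / snorm
      qDot2 <- qDot2 - beta * s2 / snorm
      qDot3 <- qDot3 - beta * s3 / snorm
      qDot4 <- qDot4 - beta * s4 / snorm
    }
  }
  q1 <- q1 + qDot1 * dt
  q2 <- q2 + qDot2 * dt
  q3 <- q3 + qDot3 * dt
  q4 <- q4 + qDot4 * dt
  n <- sqrt(q1 * q1 + q2 * q2 + q3 * q3 + q4 * q4)
  c(q1 / n, q2 / n, q3 / n, q4 / n)
}

#' One gradient-descent orientation filter update
#'
#' Predictor-corrector step: the gyroscope quaternion derivative minus
#' `gain` times the normalized gradient of the gravity + magnetic-field
#' alignment objective, integrated over `dt` and renormalized.  If the
#' accelerometer or magnetometer reading has zero norm the step degrades to
#' a gyro-only update.
#'
#' @param q Current unit quaternion (sensor to Earth), scalar first.
#' @param accel Accelerometer reading (any units; normalized internally).
#' @param gyro Gyroscope reading in deg/s.
#' @param mag Magnetometer reading (any units; normalized internally).
#' @param gain Filter gain beta (1/s); 0 gives pure gyro integration.
#' @param dt Time step (s), > 0.
#' @return Updated unit quaternion.
#' @export
fusion_step <- function(q, accel, gyro, mag, gain = 0.1, dt = 0.05) {
  if (dt <= 0) stop("dt must be > 0")
  g <- gyro * pi / 180
  use_corr <- sqrt(sum(accel^2)) > 0 && sqrt(sum(mag^2)) > 0
  marg_step(q[1], q[2], q[3], q[4], accel[1], accel[2], accel[3],
            g[1], g[2], g[3], mag[1], mag[2], mag[3],
            if (use_corr) gain else 0, dt)
}

#' Analytic orientation from one accelerometer + magnetometer sample
#'
#' TRIAD-style alignment: Earth up from the accelerometer, Earth x from the
#' horizontal component of the magnetometer.
#'
#' @param accel,mag Length-3 readings.
#' @return Unit quaternion (sensor to Earth).
#' @export
align_accel_mag <- function(accel, mag) {
  z <- accel / sqrt(sum(accel^2))
  mh <- mag - sum(mag * z) * z
  if (sqrt(sum(mh^2)) < 1e-9) return(c(1, 0, 0, 0))
  x <- mh / sqrt(sum(mh^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  # rows of R (sensor->Earth) are the Earth axes expressed in sensor frame
  quat_from_rotmat(rbind(x, y, z))
}

#' Estimate an orientation trajectory for one sensor
#'
#' Runs [fusion_step()] sequentially over a synchronized, bias-corrected
#' stream.  The initial orientation defaults to the analytic
#' accelerometer + magnetometer alignment at the first sample.
#'
#' @param stream A [sensor_stream()].
#' @param gain Filter gain beta (1/s); default 0.1, tuned for 20 Hz.
#' @param q0 Initial quaternion; default [align_accel_mag()] of sample 1.
#' @return An [orientation_series()].
#' @export
estimate_orientation <- function(stream, gain = 0.1, q0 = NULL) {
  n <- length(stream$time)
  if (n == 0)
    return(orientation_series(numeric(0), matrix(numeric(0), 0, 4),
                              gain = gain, rate = stream$rate))
  if (is.null(q0)) q0 <- align_accel_mag(stream$acc[1, ], stream$mag[1, ])
  Q <- matrix(0, n, 4)
  Q[1, ] <- q0 / sqrt(sum(q0^2))
  acc <- stream$acc; gyr <- stream$gyr * pi / 180; mag <- stream$mag
  tm <- stream$time
  q1 <- Q[1, 1]; q2 <- Q[1, 2]; q3 <- Q[1, 3]; q4 <- Q[1, 4]
  for (i in seq_len(n - 1L) + 1L) {
    dt <- tm[i] - tm[i - 1L]
    b <- gain
    if (!(acc[i, 1] != 0 || acc[i, 2] != 0 || acc[i, 3] != 0) ||
        !(mag[i, 1] != 0 || mag[i, 2] != 0 || mag[i, 3] != 0)) b <- 0
    q <- marg_step(q1, q2, q3, q4, acc[i, 1], acc[i, 2], acc[i, 3],
                   gyr[i, 1], gyr[i, 2], gyr[i, 3],
                   mag[i, 1], mag[i, 2], mag[i, 3], b, dt)
    q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
    Q[i, 1] <- q1; Q[i, 2] <- q2; Q[i, 3] <- q3; Q[i, 4] <- q4
  }
  orientation_series(tm, Q, gain = gain, rate = stream$rate)
}

#' Lumbar joint angles from two spine-sensor orientation series
#'
#' Per sample, the joint quaternion is `conj(q_lower) * q_upper` (the upper
#' sensor expressed in the lower sensor's frame), decomposed as intrinsic
#' z-y'-x'' Euler angles and reported in degrees as lateral flexion (x),
#' flexion-extension (y, forward flexion positive) and axial rotation (z).
#'
#' @param upper,lower [orientation_series()] on one common clock grid.
#' @return A [joint_angle_series()].
#' @export
joint_angles <- function(upper, lower) {
  if (length(upper$time) != length(lower$time))
    stop("orientation series lengths differ")
  if (length(upper$time) && max(abs(upper$time - lower$time)) > 1e-9)
    stop("orientation series are not on a common clock grid")
  qj <- quat_multiply_rows(quat_conjugate(lower$quat), upper$quat)
  e <- quat_to_euler(qj)
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  joint_angle_series(upper$time, rad2deg(e))
}
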