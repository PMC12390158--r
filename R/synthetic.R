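# Synthetic cohort generator: scripted standardized-task kinematics,
# free-living filler, and corrupted raw IMU streams with known ground truth.
#
# The generator realizes the measurement chain the pipeline must invert:
# a true lumbar joint angle drives two spine-segment orientations; sensors
# observe those orientations through a mounting offset, with gyro bias,
# clock skew, sensor noise and magnetic disturbance layered on top.

# ---------------------------------------------------------------------------
# Standardized-task protocol

#' Default standardized-task protocol
#'
#' Twelve tasks: four standing range-of-motion (ROM) directions, sitting ROM
#' and rotations, a sit-to-stand transition, an object pick-up, plus timed
#' standing, sitting and walking tasks.  Nine tasks have 3 repetitions with a
#' 5 s hold at the end range; the three timed tasks last 10 s.
#'
#' @return A data.frame with one row per task: `task_id`, `kind` (static /
#'   rom / timed), `reps`, `duration_s`, `axis` (primary motion axis),
#'   `amp_mean_deg` (signed end-range amplitude), `base` posture
#'   (stand / sit), and `activity` label during the task.
#' @export
default_protocol <- function() {
  data.frame(
    task_id = c("standing", "bend_forwards", "bend_backwards", "left_bend",
                "right_bend", "sitting", "slumping", "right_rotation",
                "left_rotation", "sit_to_stand", "pick_up", "walking"),
    kind = c("static", "rom", "rom", "rom", "rom", "static", "rom", "rom",
             "rom", "rom", "rom", "timed"),
    reps = c(NA, 3, 3, 3, 3, NA, 3, 3, 3, 3, 3, NA),
    duration_s = c(10, NA, NA, NA, NA, 10, NA, NA, NA, NA, NA, 10),
    axis = c("flexext", "flexext", "flexext", "latflex", "latflex",
             "flexext", "flexext", "rot", "rot", "flexext", "flexext",
             "flexext"),
    amp_mean_deg = c(0, 40, -20, -20, 20, 0, 30, -25, 25, -15, 45, 5),
    base = c("stand", "stand", "stand", "stand", "stand", "sit", "sit",
             "sit", "sit", "sit", "stand", "stand"),
    activity = c("standing", "standing", "standing", "standing", "standing",
                 "sitting", "sitting", "sitting", "sitting", "standing",
                 "standing", "stepping"),
    stringsAsFactors = FALSE
  )
}

# Timing constants of the scripted protocol (seconds).
HOP_DUR_S <- 0.15      # half-sine hop impulse duration
HOP_GAP_S <- 0.35      # gap between hops in a burst
HOP_PEAK_G <- 2        # hop peak vertical acceleration
N_HOPS <- 5            # hops per burst
BURST_MARGIN_S <- 2.5  # quiet margin around each hop burst
ROM_RAMP_S <- 1.2      # minimum-jerk ramp to/from end range
ROM_HOLD_S <- 5        # hold at end range
ROM_PAUSE_S <- 1       # pause between repetitions

# Minimum-jerk position profile on [0, 1].
min_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' Build a standardized-task script
#'
#' Lays the protocol tasks on a timeline, each preceded by a burst of 5 hops
#' with quiet margins, and records repetition sub-segments for 3-rep tasks.
#'
#' @param protocol Protocol data.frame as from [default_protocol()]; may be a
#'   subset (zero rows give an empty script).
#' @param seed Integer seed (reserved for scripted timing jitter; the default
#'   timeline is deterministic).
#' @param start_s Timeline origin in seconds.
#' @return An object of class `task_script`: list with `tasks` (task_id,
#'   kind, axis, base, activity, start_s, end_s, hop_start_s, hop_end_s),
#'   `reps` (task_id, rep, start_s, end_s), `hops` (per-hop start/end times)
#'   and `total_s`.
#' @export
build_task_script <- function(protocol = default_protocol(), seed = NULL,
                              start_s = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(protocol) > 0) {
    bad <- !is.na(protocol$duration_s) & protocol$duration_s <= 0
    if (any(bad)) stop("task durations must be > 0")
  }
  tasks <- list(); reps <- list(); hops <- list()
  t <- start_s
  burst_len <- N_HOPS * HOP_DUR_S + (N_HOPS - 1) * HOP_GAP_S
  for (i in seq_len(nrow(protocol))) {
    p <- protocol[i, ]
    hop_start <- t + BURST_MARGIN_S
    hop_t <- hop_start + (seq_len(N_HOPS) - 1) * (HOP_DUR_S + HOP_GAP_S)
    hops[[i]] <- data.frame(task_id = p$task_id, start_s = hop_t,
                            end_s = hop_t + HOP_DUR_S)
    task_start <- hop_start + burst_len + BURST_MARGIN_S
    if (p$kind %in% c("static", "timed")) {
      task_end <- task_start + p$duration_s
    } else {
      rep_len <- 2 * ROM_RAMP_S + ROM_HOLD_S
      r0 <- task_start + (0:(p$reps - 1)) * (rep_len + ROM_PAUSE_S)
      reps[[length(reps) + 1]] <- data.frame(
        task_id = p$task_id, rep = seq_len(p$reps),
        start_s = r0, end_s = r0 + rep_len)
      task_end <- r0[p$reps] + rep_len
    }
    tasks[[i]] <- data.frame(
      task_id = p$task_id, kind = p$kind, axis = p$axis, base = p$base,
      activity = p$activity, amp_mean_deg = p$amp_mean_deg,
      reps = ifelse(is.na(p$reps), 1L, as.integer(p$reps)),
      hop_start_s = hop_start, hop_end_s = hop_start + burst_len,
      start_s = task_start, end_s = task_end)
    t <- task_end + 1.5
  }
  structure(list(
    tasks = if (length(tasks)) do.call(rbind, tasks) else
      data.frame(task_id = character(0)),
    reps = if (length(reps)) do.call(rbind, reps) else
      data.frame(task_id = character(0), rep = integer(0),
                 start_s = numeric(0), end_s = numeric(0)),
    hops = if (length(hops)) do.call(rbind, hops) else
      data.frame(task_id = character(0), start_s = numeric(0),
                 end_s = numeric(0)),
    total_s = t + BURST_MARGIN_S - start_s, start_s = start_s
  ), class = "task_script")
}

#' @export
print.task_script <- function(x, ...) {
  cat(sprintf("<task_script> %d tasks, %d hop bursts, %.1f s total\n",
              nrow(x$tasks), nrow(x$hops) / N_HOPS, x$total_s))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Kinematics simulation

# Smoothly interpolate a piecewise-constant target with minimum-jerk
# transitions of length `ramp_s` starting at each change point.
smooth_steps <- function(time, change_t, values, ramp_s) {
  out <- numeric(length(time))
  cur <- values[1]
  out[] <- cur
  for (j in seq_along(change_t)) {
    tj <- change_t[j]
    idx <- time >= tj
    tau <- (time[idx] - tj) / ramp_s
    out[idx] <- cur + (values[j + 1] - cur) * min_jerk(tau)
    cur <- values[j + 1]
  }
  out
}

#' Default participant kinematic parameters
#'
#' @param neutral_flexext_deg Neutral-standing lumbar flexion angle (deg).
#' @param sit_offset_deg Additional flexion adopted when sitting (deg).
#' @param amp_sd_deg Repetition-level amplitude noise s.d. (deg).
#' @param task_style_deg Named vector (by task id) of personal posture
#'   offsets (deg) applied over each task's span; a participant trait,
#'   constant across recording conditions.  Default: none.
#' @param amp_style_deg Named vector (by task id) of personal amplitude
#'   offsets (deg) added to the task's end-range amplitude.  Default: none.
#' @export
participant_params <- function(neutral_flexext_deg = 10, sit_offset_deg = 15,
                               amp_sd_deg = 0, task_style_deg = NULL,
                               amp_style_deg = NULL) {
  list(neutral = c(latflex = 0, flexext = neutral_flexext_deg, rot = 0),
       sit_offset_deg = sit_offset_deg, amp_sd_deg = amp_sd_deg,
       task_style_deg = task_style_deg, amp_style_deg = amp_style_deg)
}

#' Simulate ground-truth kinematics for a task script
#'
#' Produces minimum-jerk lumbar joint-angle trajectories on the master clock
#' and the two spine-segment orientations consistent with them: the lower
#' segment is held upright and the upper segment carries the joint rotation,
#' so re-deriving the joint angle from the two orientation series reproduces
#' the stored angles exactly.  Hop bursts appear as vertical Earth-frame
#' linear-acceleration impulses.
#'
#' @param script A [build_task_script()] result.
#' @param params Participant parameters from [participant_params()].
#' @param seed Integer seed for repetition-level amplitude noise.
#' @param rate Sampling rate of the master clock (Hz).
#' @param condition_offset_deg Behavioral flexion offset for this recording
#'   condition (deg), added to the neutral posture.
#' @return An object of class `ground_truth`: master-clock `time`, `rate`,
#'   true `joint` angles (n x 3, deg), segment quaternions `q_lower`,
#'   `q_upper`, `q_thigh`, Earth-frame linear acceleration `lin_acc` (n x 3,
#'   g), per-second `labels`, the `script`, and an empty disturbance
#'   manifest.
#' @export
simulate_kinematics <- function(script, params = participant_params(),
                                seed = NULL, rate = 20,
                                condition_offset_deg = 0) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, ceiling(script$total_s * rate))
  time <- script$start_s + (seq_len(n) - 1) / rate
  neutral <- params$neutral
  neutral["flexext"] <- neutral["flexext"] + condition_offset_deg

  ang <- matrix(rep(neutral, each = n), ncol = 3,
                dimnames = list(NULL, c("latflex", "flexext", "rot")))
  lin <- matrix(0, n, 3)
  labels_t <- floor(time)
  labels <- rep("standing", n)

  tk <- script$tasks
  for (i in seq_len(nrow(tk))) {
    task <- tk[i, ]
    base_add <- if (task$base == "sit") params$sit_offset_deg else 0
    style <- 0
    if (!is.null(params$task_style_deg) &&
        task$task_id %in% names(params$task_style_deg))
      style <- params$task_style_deg[[task$task_id]]
    # base-posture transition (stand <-> sit) plus the personal task style,
    # ramped in over the pre-task margin and out after the task (additive,
    # so consecutive tasks stay smooth)
    extra <- base_add + style
    if (extra != 0) {
      t_on <- task$hop_start_s - BURST_MARGIN_S
      t_off <- task$end_s + 0.5
      idx <- time >= t_on & time <= t_off + 2.5
      prof <- min_jerk((time[idx] - t_on) / 2) -
        min_jerk((time[idx] - t_off) / 2)
      ang[idx, "flexext"] <- ang[idx, "flexext"] + extra * prof
    }
    in_task <- time >= task$start_s & time <= task$end_s
    labels[in_task] <- task$activity
    if (task$kind == "rom") {
      rr <- script$reps[script$reps$task_id == task$task_id, ]
      amp_style <- 0
      if (!is.null(params$amp_style_deg) &&
          task$task_id %in% names(params$amp_style_deg))
        amp_style <- params$amp_style_deg[[task$task_id]]
      for (k in seq_len(nrow(rr))) {
        amp <- task$amp_mean_deg + sign(task$amp_mean_deg) * amp_style +
          if (params$amp_sd_deg > 0) stats::rnorm(1, 0, params$amp_sd_deg) else 0
        r <- rr[k, ]
        idx <- which(time >= r$start_s & time <= r$end_s)
        tt <- time[idx] - r$start_s
        prof <- ifelse(tt < ROM_RAMP_S, min_jerk(tt / ROM_RAMP_S),
                ifelse(tt < ROM_RAMP_S + ROM_HOLD_S, 1,
                       1 - min_jerk((tt - ROM_RAMP_S - ROM_HOLD_S) / ROM_RAMP_S)))
        ang[idx, task$axis] <- ang[idx, task$axis] + amp * prof
      }
    } else if (task$kind == "timed" && task$task_id == "walking") {
      idx <- which(in_task)
      tt <- time[idx] - task$start_s
      gait_hz <- 1
      ang[idx, "flexext"] <- ang[idx, "flexext"] +
        task$amp_mean_deg * sin(2 * pi * gait_hz * tt) *
        min_jerk(tt / 1) * min_jerk((task$end_s - task$start_s - tt) / 1)
      lin[idx, ] <- lin[idx, ] + 0.15 * cbind(
        sin(2 * pi * 2 * gait_hz * tt), cos(2 * pi * 2 * gait_hz * tt),
        sin(2 * pi * 2 * gait_hz * tt + 1))
    }
  }

  # Hop impulses: vertical half-sine bursts.
  for (j in seq_len(nrow(script$hops))) {
    h <- script$hops[j, ]
    idx <- which(time >= h$start_s & time < h$end_s)
    if (length(idx))
      lin[idx, 3] <- lin[idx, 3] +
        HOP_PEAK_G * sin(pi * (time[idx] - h$start_s) / HOP_DUR_S)
  }

  gt <- kinematics_to_truth(time, rate, ang, lin, labels, script)
  gt
}

# Assemble a ground_truth object from joint angles + auxiliary tracks.
kinematics_to_truth <- function(time, rate, ang, lin, labels, script,
                                q_lower = NULL, thigh_pitch_deg = NULL) {
  n <- length(time)
  if (is.null(q_lower)) q_lower <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  a <- ang * pi / 180
  # q_joint from intrinsic z-y'-x'' Euler angles, vectorized.
  cz <- cos(a[, "rot"] / 2);     sz <- sin(a[, "rot"] / 2)
  cy <- cos(a[, "flexext"] / 2); sy <- sin(a[, "flexext"] / 2)
  cx <- cos(a[, "latflex"] / 2); sx <- sin(a[, "latflex"] / 2)
  q_joint <- cbind(
    cz * cy * cx + sz * sy * sx,
    cz * cy * sx - sz * sy * cx,
    cz * sy * cx + sz * cy * sx,
    sz * cy * cx - cz * sy * sx)
  q_upper <- quat_multiply_rows(q_lower, q_joint)
  if (is.null(thigh_pitch_deg)) {
    sit <- labels %in% c("sitting", "lying", "transport")
    thigh_pitch_deg <- ifelse(sit, 80, 0)
    # soften transitions so thigh gyro stays physical
    thigh_pitch_deg <- as.numeric(stats::filter(thigh_pitch_deg,
                                                rep(1 / (2 * rate), 2 * rate),
                                                sides = 2))
    thigh_pitch_deg[is.na(thigh_pitch_deg)] <-
      ifelse(sit, 80, 0)[is.na(thigh_pitch_deg)]
  }
  tp <- thigh_pitch_deg * pi / 180
  q_thigh <- cbind(cos(tp / 2), 0, sin(tp / 2), 0)
  lbl_sec <- data.frame(time_s = unique(floor(time)))
  lbl_sec$activity <- labels[match(lbl_sec$time_s, floor(time))]
  structure(list(
    time = time, rate = rate, joint = ang,
    q_lower = q_lower, q_upper = q_upper, q_thigh = q_thigh,
    lin_acc = lin, labels_sample = labels, labels = lbl_sec,
    script = script,
    disturbances = data.frame(start_s = numeric(0), end_s = numeric(0),
                              type = character(0), param = numeric(0))
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d samples @ %g Hz, %d tasks, %d disturbances\n",
              length(x$time), x$rate, nrow(x$script$tasks),
              nrow(x$disturbances)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# IMU synthesis

#' Default sensor noise / error parameters
#'
#' @param noise_acc_g Accelerometer white-noise s.d. (g).
#' @param noise_gyr_dps Gyroscope white-noise s.d. (deg/s).
#' @param noise_mag Magnetometer white-noise s.d. (normalized units).
#' @param skew Clock skew in samples/s relative to the master clock.
#' @param bias Gyro bias: either a length-3 constant (deg/s) or a function
#'   `f(t)` returning an n x 3 matrix of per-axis bias at times `t`.
#' @param mount Length-4 unit quaternion: sensor frame relative to its body
#'   segment (identity = perfectly aligned).
#' @param earth_field Named vector `c(magnitude, inclination_deg)`;
#'   inclination is the dip angle (negative = field pointing above the
#'   horizon, as in the southern hemisphere).
#' @export
sensor_params <- function(noise_acc_g = 0.01, noise_gyr_dps = 0.2,
                          noise_mag = 0.005, skew = 0,
                          bias = c(0, 0, 0), mount = c(1, 0, 0, 0),
                          earth_field = c(magnitude = 1, inclination_deg = -60)) {
  if (abs(sum(mount^2) - 1) > 1e-6)
    stop("mounting rotation must be a unit quaternion")
  list(noise_acc_g = noise_acc_g, noise_gyr_dps = noise_gyr_dps,
       noise_mag = noise_mag, skew = skew, bias = bias, mount = mount,
       earth_field = earth_field)
}

# Earth magnetic field vector (Earth frame, z up, x = magnetic north
# horizontal) for a dip angle `incl_deg` (positive down).
earth_field_vector <- function(magnitude, incl_deg) {
  i <- deg2rad(incl_deg)
  magnitude * c(cos(i), 0, -sin(i))
}

# Angular velocity (rad/s, sensor frame) from a row-quaternion trajectory.
angular_velocity_rows <- function(Q, rate) {
  n <- nrow(Q)
  if (n < 2) return(matrix(0, n, 3))
  dq <- quat_multiply_rows(quat_conjugate(Q[-n, , drop = FALSE]),
                           Q[-1, , drop = FALSE])
  vnorm <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vnorm, dq[, 1])
  scale <- ifelse(vnorm > 1e-12, ang / vnorm, 2) * rate
  w <- dq[, 2:4, drop = FALSE] * scale
  rbind(w, w[n - 1, , drop = FALSE])
}

# Evaluate a bias spec (constant vector or function of time) at times t.
eval_bias <- function(bias, t) {
  if (is.function(bias)) {
    b <- bias(t)
    if (is.null(dim(b))) b <- matrix(b, length(t), 3, byrow = FALSE)
    b
  } else {
    matrix(bias, length(t), 3, byrow = TRUE)
  }
}

#' Synthesize a raw IMU stream from ground truth
#'
#' Observes one body segment's true orientation through a mounting offset:
#' accelerometer = sensor-frame gravity + linear acceleration + noise,
#' gyroscope = true angular velocity + bias(t) + noise, magnetometer =
#' sensor-frame Earth field (scaled / tilted inside scripted disturbance
#' intervals) + noise.  The sensor's own clock runs at `rate + skew`
#' samples/s while claiming `rate`, so its timestamps drift linearly
#' against the master clock.
#'
#' @param truth A `ground_truth` object.
#' @param segment Which segment the sensor tracks: "lower", "upper", "thigh".
#' @param params Sensor error model from [sensor_params()].
#' @param sensor_id Sensor identity string.
#' @param seed Integer seed for measurement noise.
#' @return A [sensor_stream()] with timestamps on the sensor's own clock.
#' @export
synthesize_imu <- function(truth, segment = c("lower", "upper", "thigh"),
                           params = sensor_params(), sensor_id = segment,
                           seed = NULL) {
  segment <- match.arg(segment)
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(params$mount^2) - 1) > 1e-6)
    stop("mounting rotation must be a unit quaternion")
  rate <- truth$rate
  Qseg <- switch(segment, lower = truth$q_lower, upper = truth$q_upper,
                 thigh = truth$q_thigh)
  # Sensor orientation = segment orientation composed with mounting offset.
  n_master <- length(truth$time)
  mount <- params$mount
  M <- matrix(mount, n_master, 4, byrow = TRUE)
  Qs <- quat_multiply_rows(Qseg, M)

  # Ideal sensor-frame signals on the master grid.
  grav <- quat_rotate_inv_rows(Qs, c(0, 0, 1))
  acc_master <- grav
  if (any(truth$lin_acc != 0)) {
    # rotate Earth-frame linear acceleration into the sensor frame
    la <- truth$lin_acc
    w <- Qs[, 1]; x <- Qs[, 2]; y <- Qs[, 3]; z <- Qs[, 4]
    acc_master <- acc_master + cbind(
      (1 - 2 * (y^2 + z^2)) * la[, 1] + 2 * (x * y + w * z) * la[, 2] +
        2 * (x * z - w * y) * la[, 3],
      2 * (x * y - w * z) * la[, 1] + (1 - 2 * (x^2 + z^2)) * la[, 2] +
        2 * (y * z + w * x) * la[, 3],
      2 * (x * z + w * y) * la[, 1] + 2 * (y * z - w * x) * la[, 2] +
        (1 - 2 * (x^2 + y^2)) * la[, 3])
  }
  gyr_master <- angular_velocity_rows(Qs, rate) * 180 / pi

  # Earth field over time, with scripted disturbances applied.
  ef <- earth_field_vector(params$earth_field[["magnitude"]],
                           params$earth_field[["inclination_deg"]])
  scale <- rep(1, n_master); tilt <- rep(0, n_master)
  d <- truth$disturbances
  for (j in seq_len(nrow(d))) {
    idx <- truth$time >= d$start_s[j] & truth$time < d$end_s[j]
    if (d$type[j] %in% c("step", "sustained")) {
      scale[idx] <- 1 + d$param[j]
    } else if (d$type[j] == "tilt") {
      tilt[idx] <- d$param[j]
    }
  }
  # tilt rotates the field about the Earth y axis (changes inclination only)
  ti <- deg2rad(tilt)
  ef_t <- cbind(scale * (cos(ti) * ef[1] + sin(ti) * ef[3]),
                scale * ef[2],
                scale * (-sin(ti) * ef[1] + cos(ti) * ef[3]))
  w <- Qs[, 1]; x <- Qs[, 2]; y <- Qs[, 3]; z <- Qs[, 4]
  mag_master <- cbind(
    (1 - 2 * (y^2 + z^2)) * ef_t[, 1] + 2 * (x * y + w * z) * ef_t[, 2] +
      2 * (x * z - w * y) * ef_t[, 3],
    2 * (x * y - w * z) * ef_t[, 1] + (1 - 2 * (x^2 + z^2)) * ef_t[, 2] +
      2 * (y * z + w * x) * ef_t[, 3],
    2 * (x * z + w * y) * ef_t[, 1] + 2 * (y * z - w * x) * ef_t[, 2] +
      (1 - 2 * (x^2 + y^2)) * ef_t[, 3])

  # Sensor clock: true rate = rate + skew samples/s, claimed rate = rate.
  t0 <- truth$time[1]
  span <- truth$time[n_master] - t0
  n_s <- floor(span * (rate + params$skew)) + 1
  t_actual <- t0 + (seq_len(n_s) - 1) / (rate + params$skew)
  t_claim <- t0 + (seq_len(n_s) - 1) / rate

  interp_cols <- function(m) {
    vapply(seq_len(ncol(m)), function(j)
      stats::approx(truth$time, m[, j], xout = t_actual, rule = 2)$y,
      numeric(n_s))
  }
  acc <- interp_cols(acc_master) +
    matrix(stats::rnorm(3 * n_s, 0, params$noise_acc_g), n_s, 3)
  gyr <- interp_cols(gyr_master) + eval_bias(params$bias, t_actual) +
    matrix(stats::rnorm(3 * n_s, 0, params$noise_gyr_dps), n_s, 3)
  mag <- interp_cols(mag_master) +
    matrix(stats::rnorm(3 * n_s, 0, params$noise_mag), n_s, 3)

  sensor_stream(sensor_id, t_claim, acc, gyr, mag, rate = rate)
}

# ---------------------------------------------------------------------------
# Free-living filler

FREE_LIVING_STATES <- c("sitting", "standing", "stepping", "lying", "transport")

# Per-activity flexion posture (deg relative to neutral) and dwell means (s).
free_living_profile <- function() {
  list(
    posture = c(sitting = 18, standing = 0, stepping = 3, lying = -12,
                transport = 16),
    dwell_s = c(sitting = 300, standing = 90, stepping = 45, lying = 600,
                transport = 240),
    transition = matrix(c(
      # from\to  sit  stand step  lie  transport
                 0.0, 0.55, 0.25, 0.10, 0.10,   # sitting
                 0.45, 0.0, 0.45, 0.05, 0.05,   # standing
                 0.45, 0.45, 0.0, 0.02, 0.08,   # stepping
                 0.50, 0.40, 0.10, 0.0, 0.00,   # lying
                 0.40, 0.40, 0.20, 0.00, 0.0    # transport
    ), 5, 5, byrow = TRUE, dimnames = list(FREE_LIVING_STATES,
                                           FREE_LIVING_STATES))
  )
}

# Semi-Markov activity sequence covering `duration_s`.
simulate_activity_sequence <- function(duration_s, profile = free_living_profile(),
                                       init = "sitting") {
  state <- init; t <- 0
  states <- character(0); starts <- numeric(0); ends <- numeric(0)
  while (t < duration_s) {
    dur <- stats::rexp(1, 1 / profile$dwell_s[[state]]) + 10
    dur <- min(dur, duration_s - t)
    states <- c(states, state); starts <- c(starts, t); ends <- c(ends, t + dur)
    t <- t + dur
    state <- sample(FREE_LIVING_STATES, 1, prob = profile$transition[state, ])
  }
  data.frame(activity = states, start_s = starts, end_s = ends)
}

#' Simulate a free-living ("real-world") day with embedded task sessions
#'
#' Free-living filler is a semi-Markov chain over the five activity labels
#' (sitting, standing, stepping, lying, seated transport) with per-activity
#' lumbar postures; at a scripted time within the day the participant
#' performs the full standardized-task protocol (preceded by hop bursts).
#' Magnetic-disturbance intervals are drawn to occupy approximately
#' `disturbance_density` of the day.
#'
#' @param day_s Day duration in seconds.
#' @param task_time_s Start time of the standardized-task session within the
#'   day (default: one third in).
#' @param params Participant parameters ([participant_params()]).
#' @param condition_offset_deg Behavioral flexion offset for this day.
#' @param disturbance_density Target fraction of the day covered by magnetic
#'   disturbance intervals.
#' @param rate Master-clock sampling rate (Hz).
#' @param seed Integer seed.
#' @param start_s Timeline origin (s).
#' @return A `ground_truth` object spanning the day, with the task script
#'   embedded and a populated disturbance manifest.
#' @export
simulate_day <- function(day_s = 3600, task_time_s = day_s / 3,
                         params = participant_params(),
                         condition_offset_deg = 0,
                         disturbance_density = 0.1, rate = 20, seed = NULL,
                         start_s = 0) {
  if (!is.null(seed)) set.seed(seed)
  script <- build_task_script(start_s = start_s + task_time_s)
  stopifnot(task_time_s + script$total_s < day_s)
  n <- ceiling(day_s * rate)
  time <- start_s + (seq_len(n) - 1) / rate

  seq_pre <- simulate_activity_sequence(task_time_s)
  seq_post <- simulate_activity_sequence(day_s - task_time_s - script$total_s)
  seq_post$start_s <- seq_post$start_s + task_time_s + script$total_s
  seq_post$end_s <- seq_post$end_s + task_time_s + script$total_s
  acts <- rbind(seq_pre, seq_post)
  acts$start_s <- acts$start_s + start_s
  acts$end_s <- acts$end_s + start_s
  # tasks are performed at home: no seated transport close enough to the
  # scripted session for its exclusion padding to swallow the tasks
  near <- acts$activity == "transport" &
    acts$start_s < script$start_s + script$total_s + 360 &
    acts$end_s > script$start_s - 360
  acts$activity[near] <- "sitting"

  prof <- free_living_profile()
  neutral <- params$neutral
  neutral["flexext"] <- neutral["flexext"] + condition_offset_deg
  labels <- rep("standing", n)
  ang <- matrix(rep(neutral, each = n), ncol = 3,
                dimnames = list(NULL, c("latflex", "flexext", "rot")))
  lin <- matrix(0, n, 3)

  # free-living posture: piecewise targets with 2 s minimum-jerk transitions
  change_t <- acts$start_s
  targets <- neutral["flexext"] + prof$posture[acts$activity]
  fe <- smooth_steps(time, change_t[-1], targets, ramp_s = 2)
  for (j in seq_len(nrow(acts))) {
    idx <- time >= acts$start_s[j] & time < acts$end_s[j]
    labels[idx] <- acts$activity[j]
  }
  in_script <- time >= script$start_s & time < script$start_s + script$total_s
  ang[!in_script, "flexext"] <- fe[!in_script]
  # slow postural wander
  wander <- stats::filter(stats::rnorm(n, 0, 0.3), rep(1 / (10 * rate), 10 * rate),
                          sides = 2, circular = TRUE)
  ang[!in_script, "flexext"] <- ang[!in_script, "flexext"] +
    as.numeric(wander)[!in_script]
  # stepping micro-oscillation
  stepping <- labels == "stepping" & !in_script
  ang[stepping, "flexext"] <- ang[stepping, "flexext"] +
    3 * sin(2 * pi * 1 * time[stepping])
  lin[stepping, ] <- lin[stepping, ] + 0.1 * cbind(
    sin(2 * pi * 2 * time[stepping]), cos(2 * pi * 2 * time[stepping]),
    sin(2 * pi * 2 * time[stepping] + 1))

  # overlay scripted tasks
  task_gt <- simulate_kinematics(script, params, rate = rate,
                                 condition_offset_deg = condition_offset_deg)
  idx <- which(in_script)
  m <- min(length(idx), length(task_gt$time))
  ang[idx[seq_len(m)], ] <- task_gt$joint[seq_len(m), ]
  lin[idx[seq_len(m)], ] <- task_gt$lin_acc[seq_len(m), ]
  labels[idx[seq_len(m)]] <- task_gt$labels_sample[seq_len(m)]

  gt <- kinematics_to_truth(time, rate, ang, lin, labels, script)
  gt$disturbances <- draw_disturbances(day_s, disturbance_density,
                                       start_s = start_s,
                                       avoid = c(script$start_s,
                                                 script$start_s + script$total_s))
  gt
}

# Draw non-overlapping disturbance intervals totalling ~density * duration,
# avoiding the scripted-task window so task outcomes stay computable.
draw_disturbances <- function(duration_s, density, start_s = 0, avoid = NULL) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    type = character(0), param = numeric(0))
  if (density <= 0) return(out)
  target <- density * duration_s
  covered <- 0; tries <- 0
  while (covered < target && tries < 2000) {
    tries <- tries + 1
    type <- sample(c("step", "sustained", "tilt"), 1,
                   prob = c(0.3, 0.5, 0.2))
    dur <- switch(type,
                  step = stats::runif(1, 5, 40),
                  sustained = stats::runif(1, 40, 400),
                  tilt = stats::runif(1, 10, 120))
    dur <- min(dur, duration_s / 4)
    s <- start_s + stats::runif(1, 0, duration_s - dur)
    e <- s + dur
    if (!is.null(avoid) && s < avoid[2] + 5 && e > avoid[1] - 5) next
    if (nrow(out) && any(s < out$end_s + 2 & e > out$start_s - 2)) next
    param <- switch(type,
                    step = sample(c(1, -1), 1) * stats::runif(1, 0.35, 0.8),
                    sustained = sample(c(1, -1), 1) * stats::runif(1, 0.17, 0.28),
                    tilt = sample(c(1, -1), 1) * stats::runif(1, 35, 60))
    out <- rbind(out, data.frame(start_s = s, end_s = e, type = type,
                                 param = param))
    covered <- covered + dur
  }
  out[order(out$start_s), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Cohorts

#' Cohort specification
#'
#' Encodes the population model: participant neutral postures are drawn from
#' a between-participant distribution, each recording condition adds a
#' behavioral (within-participant) offset, and each sensor set carries its
#' own mounting misalignment.  The population ICC(A,k) of true starting
#' postures is `between_sd^2 / (between_sd^2 + within_sd^2 / k)`.
#'
#' @param n_participants Number of participants (>= 2 for ICC cohorts).
#' @param between_sd_deg Between-participant posture s.d. (deg).
#' @param within_sd_deg Within-participant between-condition s.d. (deg).
#' @param task_noise_sd_deg Repetition-level amplitude noise s.d. (deg).
#' @param style_sd_deg S.d. of the personal participant-by-task posture
#'   style (deg), constant across conditions; this is the task-specific
#'   individuality that survives session-level reference normalization.
#' @param amp_style_sd_deg S.d. of the personal participant-by-task
#'   amplitude offset (deg), constant across conditions.
#' @param mount_sd_deg Mounting-offset s.d. per sensor set (deg, about the
#'   flexion axis).
#' @param skew_range Clock skews drawn uniformly from `[-skew_range,
#'   skew_range]` samples/s.
#' @param bias_sd_dps Initial gyro-bias s.d. per axis (deg/s).
#' @param bias_drift_dps_per_h Gyro-bias linear drift rate s.d. (deg/s per
#'   hour).
#' @param disturbance_density Fraction of real-world time covered by magnetic
#'   disturbances.
#' @param day_s Real-world day duration (s); the study world is 86400, tests
#'   scale this down.
#' @param rate Sampling rate (Hz).
#' @param seed Master seed; all randomness derives from it.
#' @export
cohort_spec <- function(n_participants = 17, between_sd_deg = 8,
                        within_sd_deg = 3, task_noise_sd_deg = 2,
                        style_sd_deg = 4, amp_style_sd_deg = 5,
                        mount_sd_deg = 5, skew_range = 0.002,
                        bias_sd_dps = 0.3, bias_drift_dps_per_h = 0.05,
                        disturbance_density = 0.1, day_s = 86400,
                        rate = 20, seed = 1) {
  if (any(c(between_sd_deg, within_sd_deg, task_noise_sd_deg, style_sd_deg,
            amp_style_sd_deg, mount_sd_deg, bias_sd_dps,
            bias_drift_dps_per_h) < 0))
    stop("all standard deviations must be >= 0")
  if (disturbance_density < 0 || disturbance_density > 1)
    stop("disturbance density must be in [0, 1]")
  structure(list(
    n_participants = n_participants, between_sd_deg = between_sd_deg,
    within_sd_deg = within_sd_deg, task_noise_sd_deg = task_noise_sd_deg,
    style_sd_deg = style_sd_deg, amp_style_sd_deg = amp_style_sd_deg,
    mount_sd_deg = mount_sd_deg, skew_range = skew_range,
    bias_sd_dps = bias_sd_dps, bias_drift_dps_per_h = bias_drift_dps_per_h,
    disturbance_density = disturbance_density, day_s = day_s, rate = rate,
    seed = seed), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Per participant: one laboratory session and two real-world "days", each
#' with ground-truth kinematics; at `level = "imu"` also the raw corrupted
#' sensor streams for the two spine sensors and the thigh sensor.  At
#' `level = "angles"` only measured joint-angle series (truth viewed through
#' the session's mounting offsets) are produced — fast, for reference-method
#' and ICC studies that do not need the fusion chain.
#'
#' @param spec A [cohort_spec()].
#' @param level `"angles"` (default) or `"imu"`.
#' @param dir Optional output directory; when given, raw streams, label files
#'   and a truth manifest are written as delimited text / JSON.
#' @return A list with `spec` and `participants`; each participant holds
#'   `recordings` (named `lab`, `rw1`, `rw2`), the per-condition truth, and
#'   the drawn parameters (`neutral_deg`, condition offsets, mounting
#'   offsets, skews).
#' @export
make_cohort <- function(spec = cohort_spec(), level = c("angles", "imu"),
                        dir = NULL) {
  level <- match.arg(level)
  if (spec$n_participants < 2)
    stop("ICC-bearing cohorts need at least 2 participants")
  set.seed(spec$seed)
  conditions <- c("lab", "rw1", "rw2")
  participants <- vector("list", spec$n_participants)
  names(participants) <- sprintf("P%02d", seq_len(spec$n_participants))
  for (p in seq_len(spec$n_participants)) {
    neutral <- stats::rnorm(1, 10, spec$between_sd_deg)
    cond_off <- stats::rnorm(3, 0, spec$within_sd_deg)
    names(cond_off) <- conditions
    # one sensor set in the lab, a second set worn for both real-world days
    mount_y <- c(lab = stats::rnorm(1, 0, spec$mount_sd_deg),
                 rw = stats::rnorm(1, 0, spec$mount_sd_deg))
    task_ids <- default_protocol()$task_id
    style <- stats::rnorm(length(task_ids), 0, spec$style_sd_deg)
    names(style) <- task_ids
    amp_style <- stats::rnorm(length(task_ids), 0, spec$amp_style_sd_deg)
    names(amp_style) <- task_ids
    pp <- participant_params(neutral_flexext_deg = neutral,
                             amp_sd_deg = spec$task_noise_sd_deg,
                             task_style_deg = style,
                             amp_style_deg = amp_style)
    recs <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      set_id <- if (cond == "lab") "lab" else "rw"
      mq_up <- quat_from_axis_angle(c(0, 1, 0), deg2rad(mount_y[[set_id]]))
      mq_low <- c(1, 0, 0, 0)  # offsets differ between sets via the upper sensor
      if (cond == "lab") {
        script <- build_task_script()
        gt <- simulate_kinematics(script, pp, rate = spec$rate,
                                  condition_offset_deg = cond_off[[cond]])
        flags <- data.frame(
          event_time_s = c(script$tasks$start_s, script$tasks$end_s),
          flag_type = rep(c("start", "end"), each = nrow(script$tasks)))
      } else {
        flags <- NULL
        gt <- simulate_day(day_s = spec$day_s,
                           params = pp,
                           condition_offset_deg = cond_off[[cond]],
                           disturbance_density = spec$disturbance_density,
                           rate = spec$rate)
      }
      rec <- list(condition = cond, truth = gt, flags = flags,
                  mount = list(lower = mq_low, upper = mq_up))
      # measured joint = truth viewed through the mounting offsets
      n <- length(gt$time)
      Mlow <- matrix(mq_low, n, 4, byrow = TRUE)
      Mup <- matrix(mq_up, n, 4, byrow = TRUE)
      q_low_meas <- quat_multiply_rows(gt$q_lower, Mlow)
      q_up_meas <- quat_multiply_rows(gt$q_upper, Mup)
      qj <- quat_multiply_rows(quat_conjugate(q_low_meas), q_up_meas)
      rec$joint_measured <- joint_angle_series(gt$time, rad2deg(quat_to_euler(qj)))
      if (level == "imu") {
        skews <- stats::runif(3, -spec$skew_range, spec$skew_range)
        bias0 <- matrix(stats::rnorm(9, 0, spec$bias_sd_dps), 3, 3)
        drift <- matrix(stats::rnorm(9, 0, spec$bias_drift_dps_per_h / 3600),
                        3, 3)
        mk_bias <- function(k) {
          force(k)
          function(t) sweep(outer(t - min(t), drift[k, ]), 2, bias0[k, ], "+")
        }
        rec$streams <- list(
          l5s1 = synthesize_imu(gt, "lower",
                                sensor_params(skew = skews[1],
                                              bias = mk_bias(1),
                                              mount = mq_low),
                                sensor_id = "l5s1"),
          t12l1 = synthesize_imu(gt, "upper",
                                 sensor_params(skew = skews[2],
                                               bias = mk_bias(2),
                                               mount = mq_up),
                                 sensor_id = "t12l1"),
          thigh = synthesize_imu(gt, "thigh",
                                 sensor_params(skew = skews[3],
                                               bias = mk_bias(3)),
                                 sensor_id = "thigh"))
        rec$skews <- skews
      }
      recs[[cond]] <- rec
    }
    participants[[p]] <- list(
      id = names(participants)[p], neutral_deg = neutral,
      cond_offsets_deg = cond_off, mount_y_deg = mount_y,
      recordings = recs)
  }
  cohort <- list(spec = spec, participants = participants)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

# Write raw cohort files + truth manifest under `dir`.
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(spec = unclass(cohort$spec), participants = list())
  for (p in cohort$participants) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    pm <- list(neutral_deg = p$neutral_deg,
               cond_offsets_deg = as.list(p$cond_offsets_deg),
               mount_y_deg = as.list(p$mount_y_deg), recordings = list())
    for (rec in p$recordings) {
      rdir <- file.path(pdir, rec$condition)
      dir.create(rdir, showWarnings = FALSE)
      if (!is.null(rec$streams))
        for (s in rec$streams)
          write_sensor_table(s, file.path(rdir, paste0(s$sensor_id, ".csv")))
      data.table::fwrite(rec$truth$labels, file.path(rdir, "labels.csv"))
      write_joint_angles(rec$joint_measured,
                         file.path(rdir, "joint_truth.csv"))
      data.table::fwrite(rec$truth$script$tasks,
                         file.path(rdir, "task_windows_truth.csv"))
      pm$recordings[[rec$condition]] <- list(
        disturbances = rec$truth$disturbances,
        skews = rec$skews)
    }
    manifest$participants[[p$id]] <- pm
  }
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Build analysis-ready condition entries from a cohort's ground truth
#'
#' Bypasses the raw-sensor chain: uses each recording's measured joint
#' angles (truth seen through the session's mounting offsets) and the true
#' task windows.  This isolates the reference-normalization and
#' repeatability stages from sensor-fusion error.
#'
#' @param cohort A [make_cohort()] result (any level).
#' @return Named list (participant id) of condition-entry lists compatible
#'   with [compute_reference()] and [outcome_table()].
#' @export
cohort_conditions_from_truth <- function(cohort) {
  out <- list()
  for (p in cohort$participants) {
    conds <- list()
    for (rec in p$recordings) {
      gt <- rec$truth
      tasks <- data.frame(task_id = gt$script$tasks$task_id,
                          condition = rec$condition,
                          start_s = gt$script$tasks$start_s,
                          end_s = gt$script$tasks$end_s,
                          provenance = "truth")
      attr(tasks, "reps") <- gt$script$reps
      conds[[rec$condition]] <- list(
        condition = rec$condition,
        session = if (rec$condition == "lab") "lab" else "rw",
        joint = rec$joint_measured, tasks = tasks,
        labels = gt$labels_sample, mask = NULL)
    }
    out[[p$id]] <- conds
  }
  out
}

#' Simulate participant-by-condition outcome matrices with known ICC
#'
#' Draws `x[i, j] = mu + r_i + e_ij` with `r_i ~ N(0, between_var)` and
#' `e_ij ~ N(0, within_var)`; the population two-way absolute-agreement
#' average-measures ICC is `between_var / (between_var + within_var / k)`.
#'
#' @param n Participants (rows). @param k Conditions (columns).
#' @param icc_k Target population ICC(A,k); used to set `within_var` when
#'   variances are not given.
#' @param between_var,within_var Variance components (override `icc_k`).
#' @param mu Grand mean.
#' @return An n x k numeric matrix with attribute `icc_k` (the population
#'   value).
#' @export
simulate_icc_cohort <- function(n = 17, k = 3, icc_k = 0.7,
                                between_var = 1, within_var = NULL,
                                mu = 0) {
  if (is.null(within_var)) within_var <- k * between_var * (1 / icc_k - 1)
  r <- stats::rnorm(n, 0, sqrt(between_var))
  x <- mu + r + matrix(stats::rnorm(n * k, 0, sqrt(within_var)), n, k)
  attr(x, "icc_k") <- between_var / (between_var + within_var / k)
  x
}

#' Simulate a long multi-sensor recording for clock-drift studies
#'
#' Builds a master-clock recording of `duration_s` seconds in which the
#' sensors are still except for a burst of shared movement (smoothed
#' broadband acceleration) around every checkpoint; then resamples it with
#' per-sensor clock skews.  This exercises the hourly cross-correlation /
#' linear-drift machinery at 48 h scale without simulating full kinematics.
#'
#' @param duration_s Recording length (s), default 48 h.
#' @param skews Named numeric vector of clock skews (samples/s), one per
#'   sensor; the first sensor is conventionally the reference with skew 0.
#' @param rate Nominal rate (Hz).
#' @param burst_every_s Spacing of movement bursts (s).
#' @param burst_len_s Burst duration (s).
#' @param noise_acc_g Per-sensor independent accelerometer noise (g).
#' @param seed Integer seed.
#' @return Named list of [sensor_stream()]s.
#' @export
simulate_drift_recording <- function(duration_s = 48 * 3600,
                                     skews = c(ref = 0, a = 0.001),
                                     rate = 20, burst_every_s = 3600,
                                     burst_len_s = 90,
                                     noise_acc_g = 0.005, seed = 1) {
  set.seed(seed)
  n <- ceiling(duration_s * rate)
  t_master <- (seq_len(n) - 1) / rate
  # shared movement signal: smoothed broadband bursts at each checkpoint
  shared <- matrix(0, n, 3)
  centers <- seq(min(burst_every_s / 2, duration_s / 2), duration_s,
                 by = burst_every_s)
  for (ct in centers) {
    idx <- which(t_master >= ct - burst_len_s / 2 &
                 t_master < ct + burst_len_s / 2)
    m <- length(idx)
    raw <- matrix(stats::rnorm(3 * m, 0, 0.3), m, 3)
    for (j in 1:3)
      raw[, j] <- as.numeric(stats::filter(raw[, j], rep(0.2, 5),
                                           circular = TRUE))
    shared[idx, ] <- raw
  }
  out <- list()
  for (si in seq_along(skews)) {
    s <- skews[si]
    n_s <- floor(duration_s * (rate + s)) + 1
    t_actual <- (seq_len(n_s) - 1) / (rate + s)
    acc <- vapply(1:3, function(j)
      stats::approx(t_master, shared[, j], xout = t_actual, rule = 2)$y,
      numeric(n_s))
    acc[, 3] <- acc[, 3] + 1  # gravity
    acc <- acc + matrix(stats::rnorm(3 * n_s, 0, noise_acc_g), n_s, 3)
    gyr <- matrix(stats::rnorm(3 * n_s, 0, 0.1), n_s, 3)
    mag <- matrix(rep(earth_field_vector(1, -60), each = n_s), n_s, 3) +
      matrix(stats::rnorm(3 * n_s, 0, 0.005), n_s, 3)
    out[[names(skews)[si]]] <- sensor_stream(
      names(skews)[si], (seq_len(n_s) - 1) / rate, acc, gyr, mag, rate = rate)
  }
  out
}
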