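earth_mag <- spinewear:::earth_field_vector(1, -60)

test_that("the aligned stationary state is a fixed point of the filter", {
  q <- fusion_step(c(1, 0, 0, 0), accel = c(0, 0, 1), gyro = c(0, 0, 0),
                   mag = earth_mag, gain = 0.1, dt = 0.05)
  expect_equal(q, c(1, 0, 0, 0), tolerance = 1e-12)
  expect_error(fusion_step(c(1, 0, 0, 0), c(0, 0, 1), c(0, 0, 0),
                           earth_mag, dt = 0), "dt")
})

test_that("gain 0 reduces to closed-form gyro integration", {
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    w_dps <- 36
    q <- c(1, 0, 0, 0)
    for (i in 1:100)
      q <- fusion_step(q, c(0, 0, 0), w_dps * axis, c(0, 0, 0),
                       gain = 0, dt = 0.05)
    # 36 deg/s * 5 s = 180 deg about the axis
    q_true <- quat_from_axis_angle(axis, spinewear:::deg2rad(180))
    expect_lt(spinewear:::rad2deg(quat_angle_between(q, q_true)), 0.1)
  }
})

test_that("the filter converges from a wrong initial orientation", {
  q_true <- quat_from_euler(0.4, 0.3, -0.2)
  acc <- as.numeric(spinewear:::quat_rotate_inv_rows(matrix(q_true, 1),
                                                     c(0, 0, 1)))
  mag <- as.numeric(spinewear:::quat_rotate_inv_rows(matrix(q_true, 1),
                                                     earth_mag))
  q <- c(1, 0, 0, 0)
  for (i in 1:600)  # 30 s at 20 Hz
    q <- fusion_step(q, acc, c(0, 0, 0), mag, gain = 0.1, dt = 0.05)
  expect_lt(spinewear:::rad2deg(quat_angle_between(q, q_true)), 2)
})

test_that("unit norm is conserved at every step", {
  set.seed(61)
  q <- quat_normalize(stats::rnorm(4))
  for (i in 1:200) {
    q <- fusion_step(q, stats::rnorm(3), stats::rnorm(3, 0, 50),
                     stats::rnorm(3), gain = 0.2, dt = 0.05)
    expect_equal(sum(q^2), 1, tolerance = 1e-9)
  }
})

test_that("zero-norm accel or mag degrades to a gyro-only step", {
  q0 <- quat_from_euler(0.2, 0.1, 0)
  q1 <- fusion_step(q0, c(0, 0, 0), c(10, 0, 0), c(0, 0, 0),
                    gain = 0.5, dt = 0.05)
  q2 <- fusion_step(q0, c(0, 0, 0), c(10, 0, 0), c(0, 0, 0),
                    gain = 0, dt = 0.05)
  expect_equal(q1, q2)
})

test_that("estimate_orientation is deterministic and handles empty input", {
  st <- make_still_stream(100, q = quat_from_euler(0.3, 0.2, 0.1))
  o1 <- estimate_orientation(st)
  o2 <- estimate_orientation(st)
  expect_identical(o1$quat, o2$quat)
  empty <- sensor_stream("e", numeric(0), matrix(0, 0, 3),
                         matrix(0, 0, 3), matrix(0, 0, 3))
  expect_equal(length(estimate_orientation(empty)$time), 0)
})

test_that("a stationary noisy stream holds its heading for 10 minutes", {
  set.seed(62)
  st <- make_still_stream(12000, q = quat_from_euler(0.5, 0.1, 0),
                          noise = 0.01)
  os <- estimate_orientation(st)
  yaw <- spinewear:::rad2deg(quat_to_euler(os$quat)[, "z"])
  # drift = shift of the mean heading between the first and last 30 s
  # (after warm-up); sample-to-sample noise jitter is not drift
  early <- st$time > 10 & st$time <= 40
  late <- st$time > max(st$time) - 30
  expect_lt(abs(mean(yaw[late]) - mean(yaw[early])), 1)
})

test_that("joint angles: identity, single-axis rotation, and round-trip", {
  n <- 10
  tm <- (1:n) / 20
  qI <- matrix(rep(c(1, 0, 0, 0), each = n), ncol = 4)
  lower <- orientation_series(tm, qI)
  expect_equal(max(abs(joint_angles(lower, lower)$angles)), 0)
  # upper rotated +30 deg about the flexion (y) axis
  qU <- matrix(rep(quat_from_axis_angle(c(0, 1, 0),
                                        spinewear:::deg2rad(30)), each = n),
               ncol = 4)
  j <- joint_angles(orientation_series(tm, qU), lower)
  expect_equal(j$angles[, "flexext"], rep(30, n), tolerance = 1e-6)
  expect_lt(max(abs(j$angles[, c("latflex", "rot")])), 1e-6)
  # composing the reported angles reproduces the joint quaternion
  set.seed(63)
  for (i in 1:20) {
    ql <- quat_normalize(stats::rnorm(4))
    qu <- quat_normalize(stats::rnorm(4))
    qj <- quat_multiply(quat_conjugate(ql), qu)
    e <- quat_to_euler(qj)
    q_back <- quat_from_euler(e[["z"]], e[["y"]], e[["x"]])
    expect_lt(min(sum((qj - q_back)^2), sum((qj + q_back)^2)), 1e-18)
  }
  expect_error(joint_angles(orientation_series(tm[1:5], qU[1:5, ]), lower),
               "lengths differ")
})

test_that("joint angles are invariant to a common Earth-frame rotation", {
  set.seed(64)
  n <- 50
  tm <- (1:n) / 20
  ql <- t(vapply(1:n, function(i) quat_from_euler(0.01 * i, 0.02 * i, 0),
                 numeric(4)))
  qu <- t(vapply(1:n, function(i) quat_from_euler(0.02 * i, -0.01 * i, 0.005 * i),
                 numeric(4)))
  j0 <- joint_angles(orientation_series(tm, qu), orientation_series(tm, ql))
  g <- quat_from_axis_angle(stats::rnorm(3), 1.1)  # common Earth rotation
  G <- matrix(g, n, 4, byrow = TRUE)
  j1 <- joint_angles(
    orientation_series(tm, spinewear:::quat_multiply_rows(G, qu)),
    orientation_series(tm, spinewear:::quat_multiply_rows(G, ql)))
  expect_lt(max(abs(j1$angles - j0$angles)), 1e-6)
})

test_that("scripted kinematics are recovered through the full IMU chain", {
  script <- build_task_script()
  gt <- simulate_kinematics(script, participant_params(amp_sd_deg = 0))
  sp0 <- sensor_params(noise_acc_g = 0, noise_gyr_dps = 0, noise_mag = 0)
  lower <- estimate_orientation(synthesize_imu(gt, "lower", sp0, "l5s1"))
  upper <- estimate_orientation(synthesize_imu(gt, "upper", sp0, "t12l1"))
  j <- joint_angles(upper, lower)
  m <- min(length(j$time), length(gt$time))
  warm <- gt$time[1:m] > gt$time[1] + 10
  err <- j$angles[1:m, "flexext"][warm] - gt$joint[1:m, "flexext"][warm]
  expect_lt(sqrt(mean(err^2)), 2)
  # per-task ROM within 1 degree of the scripted amplitude
  for (i in which(script$tasks$kind == "rom")) {
    w <- script$tasks[i, ]
    idx <- j$time >= w$start_s & j$time <= w$end_s
    rom <- diff(range(j$angles[idx, w$axis]))
    expect_equal(rom, abs(w$amp_mean_deg), tolerance = 1)
  }
})
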