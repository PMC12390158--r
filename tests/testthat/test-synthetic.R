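test_that("task script covers the 12-task protocol with hop bursts", {
  script <- build_task_script()
  expect_equal(nrow(script$tasks), 12)
  expect_equal(sum(script$tasks$reps == 3), 9)  # 9 three-rep tasks
  expect_equal(sum(script$tasks$kind %in% c("static", "timed")), 3)
  expect_equal(nrow(script$hops), 12 * 5)       # 5 hops before every task
  # segments non-overlapping and time ordered
  expect_true(all(diff(script$tasks$start_s) > 0))
  expect_true(all(script$tasks$end_s[-12] <= script$tasks$start_s[-1]))
  # every hop burst precedes its task
  expect_true(all(script$tasks$hop_end_s < script$tasks$start_s))
  # 10 s timed tasks
  timed <- script$tasks$kind %in% c("static", "timed")
  expect_equal(script$tasks$end_s[timed] - script$tasks$start_s[timed],
               rep(10, 3))
})

test_that("task script handles empty protocols and rejects bad durations", {
  empty <- build_task_script(default_protocol()[0, ])
  expect_equal(nrow(empty$tasks), 0)
  bad <- default_protocol()
  bad$duration_s[1] <- -1
  expect_error(build_task_script(bad), "duration")
})

test_that("scripts and kinematics are deterministic given a seed", {
  s1 <- build_task_script(seed = 3)
  s2 <- build_task_script(seed = 3)
  expect_identical(s1, s2)
  p <- participant_params(amp_sd_deg = 2)
  g1 <- simulate_kinematics(s1, p, seed = 9)
  g2 <- simulate_kinematics(s1, p, seed = 9)
  expect_identical(g1$joint, g2$joint)
  g3 <- simulate_kinematics(s1, p, seed = 10)
  expect_false(identical(g1$joint, g3$joint))  # rep noise differs
  # same task order regardless of seed
  expect_identical(g1$script$tasks$task_id, g3$script$tasks$task_id)
})

test_that("scripted amplitudes appear in the true joint angle", {
  script <- build_task_script()
  gt <- simulate_kinematics(script, participant_params(amp_sd_deg = 0))
  w <- script$tasks[script$tasks$task_id == "slumping", ]
  idx <- gt$time >= w$start_s & gt$time <= w$end_s
  expect_equal(diff(range(gt$joint[idx, "flexext"])), 30, tolerance = 0.1)
})

test_that("zero-amplitude protocol gives a constant neutral joint angle", {
  proto <- default_protocol()
  proto$amp_mean_deg[] <- 0
  script <- build_task_script(proto)
  gt <- simulate_kinematics(script,
                            participant_params(neutral_flexext_deg = 7,
                                               sit_offset_deg = 0))
  expect_equal(range(gt$joint[, "flexext"]), c(7, 7), tolerance = 1e-9)
  expect_equal(range(gt$joint[, "latflex"]), c(0, 0), tolerance = 1e-9)
})

test_that("ground truth joint angle is consistent with the orientations", {
  gt <- simulate_kinematics(build_task_script(),
                            participant_params(amp_sd_deg = 2), seed = 4)
  qj <- spinewear:::quat_multiply_rows(spinewear:::quat_conjugate(gt$q_lower),
                                       gt$q_upper)
  rederived <- spinewear:::rad2deg(quat_to_euler(qj))
  expect_lt(max(abs(rederived - gt$joint)), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(gt$q_upper^2)) - 1)), 1e-9)
})

test_that("noise-free stationary IMU reads 1 g and the true field", {
  proto0 <- default_protocol()[1, ]  # standing 10 s
  proto0$amp_mean_deg <- 0
  gt <- simulate_kinematics(build_task_script(proto0),
                            participant_params(sit_offset_deg = 0))
  gt$lin_acc[] <- 0  # drop the hops: pure stationarity
  st <- synthesize_imu(gt, "lower",
                       sensor_params(noise_acc_g = 0, noise_gyr_dps = 0,
                                     noise_mag = 0))
  expect_equal(sqrt(rowSums(st$acc^2)), rep(1, length(st$time)),
               tolerance = 1e-9)
  expect_equal(sqrt(rowSums(st$mag^2)), rep(1, length(st$time)),
               tolerance = 1e-9)
})

test_that("injected constant gyro bias appears in the synthesized stream", {
  proto0 <- default_protocol()[1, ]
  proto0$amp_mean_deg <- 0
  gt <- simulate_kinematics(build_task_script(proto0),
                            participant_params(sit_offset_deg = 0))
  gt$lin_acc[] <- 0
  set.seed(1)
  st <- synthesize_imu(gt, "lower",
                       sensor_params(bias = c(0.5, 0, 0),
                                     noise_gyr_dps = 0.2), seed = 1)
  n <- length(st$time)
  ci <- 3 * 0.2 / sqrt(n)
  expect_lt(abs(mean(st$gyr[, 1]) - 0.5), ci)
  expect_lt(abs(mean(st$gyr[, 2])), ci)
})

test_that("magnetic disturbance steps scale the magnetometer by construction", {
  proto0 <- default_protocol()[1, ]
  proto0$amp_mean_deg <- 0
  gt <- simulate_kinematics(build_task_script(proto0),
                            participant_params(sit_offset_deg = 0))
  gt$disturbances <- data.frame(start_s = 5, end_s = 8, type = "step",
                                param = 0.4)
  st <- synthesize_imu(gt, "lower",
                       sensor_params(noise_acc_g = 0, noise_gyr_dps = 0,
                                     noise_mag = 0))
  inside <- st$time >= 5 & st$time < 8
  mnorm <- sqrt(rowSums(st$mag^2))
  expect_equal(mnorm[inside], rep(1.4, sum(inside)), tolerance = 1e-6)
  expect_equal(mnorm[!inside], rep(1, sum(!inside)), tolerance = 1e-6)
})

test_that("sensor clocks drift by skew x time against the master clock", {
  proto0 <- default_protocol()[1, ]
  gt <- simulate_kinematics(build_task_script(proto0), participant_params())
  skew <- 0.002
  st <- synthesize_imu(gt, "lower", sensor_params(skew = skew,
                                                  noise_acc_g = 0,
                                                  noise_gyr_dps = 0,
                                                  noise_mag = 0))
  expect_true(all(diff(st$time) > 0))
  # drift: the sensor records duration * (rate + skew) samples but claims
  # them at the nominal rate
  span <- max(gt$time) - min(gt$time)
  expected_extra <- floor(span * (20 + skew)) - floor(span * 20)
  expect_equal(length(st$time) - length(gt$time), expected_extra)
})

test_that("non-unit mounting rotations are rejected", {
  expect_error(sensor_params(mount = c(1, 1, 0, 0)), "unit quaternion")
})

test_that("cohort spec validates its variance and density fields", {
  expect_error(cohort_spec(between_sd_deg = -1), ">= 0")
  expect_error(cohort_spec(disturbance_density = 1.5), "\\[0, 1\\]")
  expect_error(make_cohort(cohort_spec(n_participants = 1)), "at least 2")
})

test_that("icc cohort generator hits its analytic population value", {
  # between var 1, within var 1, k conditions: ICC(A,k) = 1 / (1 + 1/k)
  x <- simulate_icc_cohort(n = 10, k = 4, between_var = 1, within_var = 1)
  expect_equal(attr(x, "icc_k"), 1 / (1 + 1 / 4))
  # degenerate: no within variance -> population ICC 1
  y <- simulate_icc_cohort(n = 5, k = 3, between_var = 4, within_var = 0)
  expect_equal(attr(y, "icc_k"), 1)
  expect_equal(stats::sd(y[, 1] - y[, 2]), 0)
})

test_that("cohort generation is reproducible and writes readable files", {
  spec <- cohort_spec(n_participants = 2, day_s = 700,
                      disturbance_density = 0, seed = 5)
  c1 <- make_cohort(spec, level = "angles")
  c2 <- make_cohort(spec, level = "angles")
  expect_identical(c1$participants$P01$recordings$rw1$joint_measured$angles,
                   c2$participants$P01$recordings$rw1$joint_measured$angles)
  dir <- withr::local_tempdir()
  make_cohort(spec, level = "angles", dir = dir)
  expect_true(file.exists(file.path(dir, "truth_manifest.json")))
  expect_true(file.exists(file.path(dir, "P01", "lab", "joint_truth.csv")))
})
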