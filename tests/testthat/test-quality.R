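# A still stream with controllable magnetometer magnitude / inclination.
field_stream <- function(duration_s = 120, rate = 20, scale = NULL,
                         incl_deg = NULL, base_incl = -60) {
  n <- duration_s * rate + 1
  tm <- (seq_len(n) - 1) / rate
  if (is.null(scale)) scale <- rep(1, n)
  incl <- if (is.null(incl_deg)) rep(base_incl, n) else incl_deg
  m <- t(vapply(seq_len(n), function(i)
    scale[i] * spinewear:::earth_field_vector(1, incl[i]), numeric(3)))
  sensor_stream("f", tm, cbind(0, 0, rep(1, n)), matrix(0, n, 3), m,
                rate = rate)
}

test_that("field reference is estimated from stillness or passed through", {
  st <- field_stream(60)
  still <- detect_stillness(st)
  ref <- estimate_field_reference(st, still)
  expect_equal(ref$magnitude, 1, tolerance = 1e-6)
  expect_equal(ref$inclination_deg, -60, tolerance = 0.5)
  user <- estimate_field_reference(st, user = c(0.9, -45))
  expect_equal(user$magnitude, 0.9)
  expect_equal(user$provenance, "user")
  expect_error(estimate_field_reference(st, still[0, ]),
               "configuration error")
})

test_that("disagreeing spine references raise a consistency warning", {
  a <- estimate_field_reference(NULL, user = c(1.0, -60))
  b <- estimate_field_reference(NULL, user = c(1.3, -60))
  expect_warning(check_field_consistency(a, b), "disagree")
  expect_silent(check_field_consistency(a, a))
})

test_that("the instantaneous 30% magnitude rule flags from the first sample", {
  n <- 120 * 20 + 1
  scale <- rep(1, n); scale[801:1000] <- 1.4
  st <- field_stream(120, scale = scale)
  ref <- estimate_field_reference(NULL, user = c(1, -60))
  fl <- detect_magnetic_disturbance(st, ref)
  expect_equal(which(fl), 801:1000)
  rules <- attr(fl, "rules")
  expect_true(all(rules[801:1000, "instant"]))
  expect_false(any(rules[, "sustained"] & !rules[, "instant"]))
  # a +20% step of 10 s is NOT flagged
  scale2 <- rep(1, n); scale2[801:1000] <- 1.2
  expect_false(any(detect_magnetic_disturbance(field_stream(120, scale = scale2),
                                               ref)))
})

test_that("the sustained 15%/30 s rule flags whole runs", {
  n <- 120 * 20 + 1
  scale <- rep(1, n)
  scale[501:(501 + 35 * 20)] <- 1.2  # +20% for 35 s
  st <- field_stream(120, scale = scale)
  ref <- estimate_field_reference(NULL, user = c(1, -60))
  fl <- detect_magnetic_disturbance(st, ref)
  expect_equal(which(fl), 501:(501 + 35 * 20))
})

test_that("the 30 deg inclination rule triggers at constant magnitude", {
  n <- 120 * 20 + 1
  incl <- rep(-60, n); incl[1001:1400] <- -60 + 35
  st <- field_stream(120, incl_deg = incl)
  ref <- estimate_field_reference(NULL, user = c(1, -60))
  fl <- detect_magnetic_disturbance(st, ref)
  expect_equal(which(fl), 1001:1400)
  # magnitude untouched: neither magnitude rule fires
  rules <- attr(fl, "rules")
  expect_false(any(rules[, "instant"]))
  expect_true(all(rules[1001:1400, "inclination"]))
})

test_that("clean simulations produce zero false positives", {
  set.seed(81)
  gt <- simulate_day(day_s = 700, task_time_s = 180,
                     disturbance_density = 0, seed = 81)
  st <- synthesize_imu(gt, "lower", sensor_params(), "l5s1", seed = 2)
  cb <- correct_gyro_bias(st)
  ref <- estimate_field_reference(st, cb$intervals)
  fl <- detect_magnetic_disturbance(st, ref)
  expect_equal(sum(fl), 0)
})

test_that("flagged samples match the simulator's disturbance manifest", {
  gt <- simulate_day(day_s = 1500, task_time_s = 400,
                     disturbance_density = 0.15, seed = 82)
  expect_gt(nrow(gt$disturbances), 0)
  st <- synthesize_imu(gt, "lower", sensor_params(), "l5s1", seed = 3)
  cb <- correct_gyro_bias(st)
  ref <- estimate_field_reference(st, cb$intervals)
  fl <- detect_magnetic_disturbance(st, ref)
  truth <- rep(FALSE, length(st$time))
  for (i in seq_len(nrow(gt$disturbances)))
    truth[st$time >= gt$disturbances$start_s[i] &
          st$time < gt$disturbances$end_s[i]] <- TRUE
  # within +/- 2 samples at each interval edge
  mism <- which(fl != truth)
  if (length(mism)) {
    edges <- c(outer(c(gt$disturbances$start_s, gt$disturbances$end_s) * 20,
                     -2:2, `+`))
    expect_true(all(mism %in% round(edges + 1)))
  }
  expect_lt(abs(mean(fl) - mean(truth)), 0.001)
})

test_that("transport exclusion pads by 5 minutes and clamps at bounds", {
  rate <- 20
  tm <- seq(0, 3599.95, by = 1 / rate)
  labels <- rep("sitting", length(tm))
  labels[tm >= 1500 & tm < 2100] <- "transport"  # 10 min mid-recording
  fl <- exclude_transport(labels, tm)
  expect_equal(range(tm[fl]), c(1200, 2400 - 1 / rate), tolerance = 0.051)
  expect_equal(sum(fl) / rate, 1200, tolerance = 1)  # 20 min flagged
  # at the recording start the pad is clamped
  labels2 <- rep("sitting", length(tm))
  labels2[tm < 60] <- "transport"
  fl2 <- exclude_transport(labels2, tm)
  expect_equal(min(tm[fl2]), 0)
  expect_equal(max(tm[fl2]), 360 - 1 / rate, tolerance = 0.051)
  # no transport, no flags
  expect_equal(sum(exclude_transport(rep("sitting", 100), (1:100) / 20)), 0)
})

test_that("non-physiological flags use strict inequalities", {
  tm <- (1:5) / 20
  j <- joint_angle_series(tm, cbind(0, c(75, 70, -50, -50.01, 0), 0))
  fl <- exclude_nonphysiological(j)
  expect_equal(fl, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("combined masks satisfy the union inequalities", {
  n <- 1000
  a <- seq_len(n) <= 100          # 10%
  b <- seq_len(n) > 900           # disjoint 10%
  m <- combine_masks(magnetic = a, transport = b,
                     nonphysiological = logical(n))
  expect_equal(unname(m$fractions[["union"]]), 0.2)
  # idempotence: identical flags don't double count
  m2 <- combine_masks(magnetic = a, transport = a,
                      nonphysiological = logical(n))
  expect_equal(unname(m2$fractions[["union"]]), 0.1)
  expect_equal(m2$overlap_transport_magnetic, 1)
  # invariants on random masks
  set.seed(83)
  for (i in 1:20) {
    f <- matrix(stats::runif(3 * n) < 0.2, n, 3)
    mm <- combine_masks(f[, 1], f[, 2], f[, 3])
    expect_gte(mm$fractions[["union"]], max(mm$fractions[1:3]))
    expect_lte(mm$fractions[["union"]], min(1, sum(mm$fractions[1:3])))
  }
  expect_error(combine_masks(a, b[1:10], logical(n)), "lengths differ")
})

test_that("quality reports serialize the fractions and intervals", {
  n <- 200
  fl <- c(rep(FALSE, 50), rep(TRUE, 50), rep(FALSE, 100))
  m <- combine_masks(magnetic = fl, transport = logical(n),
                     nonphysiological = logical(n), time = (1:n) / 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_quality_report(m, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$fractions$magnetic, 0.25)
  expect_equal(nrow(rep$intervals), 1)
})
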