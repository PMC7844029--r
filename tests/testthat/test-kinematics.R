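flat_stream <- function(a, n = 60, rate = 30) {
  accel_stream(seq(0, by = 1 / rate, length.out = n),
               matrix(rep(a, each = n), nrow = n))
}

test_that("calibration recovers the closed-form angles and a valid rotation", {
  cal0 <- calibrate_imu(flat_stream(c(0, 0, 1)))
  expect_equal(cal0$theta_r, 0)
  expect_equal(cal0$theta_p, 0)
  expect_equal(cal0$R, diag(3))
  phi <- 0.3
  cal <- calibrate_imu(flat_stream(c(0, sin(phi), cos(phi))))
  expect_equal(cal$theta_r, phi)
  expect_equal(cal$theta_p, 0, tolerance = 1e-12)
  # random mounting orientation: R maps the calibration vector onto +z
  sim <- simulate_accelerometer(0, 0, calib_orientation = c(0.7, -0.4))
  calr <- calibrate_imu(sim$calibration_segment)
  expect_lt(max(abs(calr$R %*% calr$a_calib - c(0, 0, 1))), 1e-9)
  expect_lt(max(abs(t(calr$R) %*% calr$R - diag(3))), 1e-10)
  expect_equal(det(calr$R), 1)
})

test_that("near-zero gravity or too-short segments invalidate calibration", {
  expect_error(calibrate_imu(flat_stream(c(0, 0, 0.2))), "0.5 g")
  expect_error(calibrate_imu(flat_stream(c(0, 0, 1), n = 10)), ">= 1 s")
})

test_that("pitch/roll recovery inverts the accelerometer simulator", {
  g <- expand.grid(p = seq(-50, 50, by = 5), r = seq(-50, 50, by = 5))
  sim <- simulate_accelerometer(g$p, g$r, calib_orientation = c(0.25, -0.15))
  cal <- calibrate_imu(sim$calibration_segment)
  rec <- compute_pitch_roll(sim$stream, cal)
  expect_lt(max(abs(rec$H_p - g$p)), 1e-6)
  expect_lt(max(abs(rec$H_r - g$r)), 1e-6)
  # head-fixed posture reads exactly zero
  sim0 <- simulate_accelerometer(0, 0, calib_orientation = c(0.25, -0.15))
  rec0 <- compute_pitch_roll(sim0$stream, cal)
  expect_equal(rec0$H_p, 0, tolerance = 1e-9)
  expect_equal(rec0$H_r, 0, tolerance = 1e-9)
})

test_that("gimbal-adjacent commanded angles are rejected", {
  expect_error(simulate_accelerometer(90, 0), "gimbal")
  expect_error(simulate_accelerometer(0, -95), "gimbal")
})

test_that("sensor noise keeps recovered static angles under one degree SD", {
  n <- 70 * 60 * 30  # 70 min at 30 Hz
  sim <- simulate_accelerometer(rep(0, n), rep(0, n),
                                calib_orientation = c(0.2, 0.1),
                                noise_sd = 0.005, seed = 8)
  rec <- compute_pitch_roll(sim$stream, calibrate_imu(sim$calibration_segment))
  expect_lt(sd(rec$H_p), 1)
  expect_lt(sd(rec$H_r), 1)
  # slow drift below one noise SD moves the recovered angles < 1 degree
  simd <- simulate_accelerometer(rep(0, 3000), rep(0, 3000),
                                 drift = c(0.004, 0, 0))
  recd <- compute_pitch_roll(simd$stream,
                             calibrate_imu(simd$calibration_segment))
  expect_lt(max(abs(recd$H_p)), 1)
  expect_lt(max(abs(recd$H_r)), 1)
})

test_that("LED variables: midpoint, atan2 convention, speed", {
  led1 <- rbind(c(0, 0), c(0, 0), c(3, 0))
  led2 <- rbind(c(0, 2), c(0, 2), c(3, 2))
  out <- compute_led_variables(led1, led2, sample_rate = 50)
  expect_equal(out$B_x[1], 0)
  expect_equal(out$B_y[1], 1)
  # difference vector led1 - led2 along -y -> 270; along +y -> 90
  expect_equal(out$H_a[1], 270)
  out2 <- compute_led_variables(led2, led1, sample_rate = 50)
  expect_equal(out2$H_a[1], 90)
  # stationary then a 3 cm step in one 20 ms frame
  expect_equal(out$B_s[2], 0)
  expect_equal(out$B_s[3], 150)
  # missing LED samples are masked
  led1[2, ] <- NA
  out3 <- compute_led_variables(led1, led2, 50)
  expect_false(out3$valid[2])
})

test_that("angular velocity uses the shortest signed arc", {
  v <- compute_angular_velocities(c(359, 1), 50, circular = TRUE)
  expect_equal(v[2], 100)   # +2 deg per 20 ms frame, not -358
  expect_equal(compute_angular_velocities(rep(42, 10), 50, circular = TRUE),
               rep(0, 10))
  ramp <- (seq(0, 10, by = 0.2) * 10) %% 360   # 10 deg/s at 50 Hz... scaled
  t <- seq(0, 2, by = 0.02)
  v2 <- compute_angular_velocities((10 * t) %% 360, 50, circular = TRUE)
  expect_equal(v2, rep(10, length(t)), tolerance = 1e-9)
  # wrapped difference is always bounded by half a turn per frame
  set.seed(3)
  vr <- compute_angular_velocities(runif(500, 0, 360), 50, circular = TRUE)
  expect_lte(max(abs(vr)) * 0.02, 180)
})

test_that("synchronization interpolates linearly and conserves spikes", {
  led_t <- seq(0, 10, by = 0.02)
  imu_t <- seq(0, 10, by = 1 / 30)
  ramp <- 3 * imu_t + 1
  set.seed(9)
  spikes <- sort(runif(200, 0, 10))
  out <- synchronize_and_bin(led_t, imu_t, list(r = ramp), spikes)
  expect_equal(out$channels$r, 3 * led_t + 1, tolerance = 1e-10)
  expect_equal(sum(out$counts), sum(spikes >= 0 & spikes < length(led_t) * 0.02))
  # half-open binning: a spike at 0.030 s lands in bin [0.02, 0.04)
  one <- synchronize_and_bin(led_t, imu_t, list(), 0.030)
  expect_equal(which(one$counts == 1), 2L)
  edge <- synchronize_and_bin(led_t, imu_t, list(), 0.040)
  expect_equal(which(edge$counts == 1), 3L)
})

test_that("unmatched sync pulses fail synchronization", {
  expect_error(
    synchronize_and_bin(seq(0, 1, 0.02), seq(0, 1, 1 / 30), list(),
                        numeric(), led_pulses = c(0, 1),
                        imu_pulses = c(0, 0.5, 1)),
    "unmatched pulse")
  # a clock offset is corrected through matched pulses
  out <- synchronize_and_bin(seq(0, 10, 0.02), seq(5, 15, 1 / 30),
                             list(r = 2 * seq(5, 15, 1 / 30)),
                             numeric(), led_pulses = c(0, 10),
                             imu_pulses = c(5, 15))
  expect_equal(out$channels$r, 2 * (seq(0, 10, 0.02) + 5), tolerance = 1e-9)
})
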