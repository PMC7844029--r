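#' Roll and pitch rotation matrices
#'
#' Right-handed rotations about the x (roll) and y (pitch) axes used to
#' relate the sensor frame to the head frame.
#' @param theta Angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_roll <- function(theta) {
  rbind(c(1, 0, 0),
        c(0, cos(theta), sin(theta)),
        c(0, -sin(theta), cos(theta)))
}

#' @rdname rot_roll
#' @keywords internal
rot_pitch <- function(theta) {
  rbind(c(cos(theta), 0, -sin(theta)),
        c(0, 1, 0),
        c(sin(theta), 0, cos(theta)))
}

#' Construct an accelerometer stream
#'
#' @param timestamps Strictly increasing sample times (s); ~30 Hz and
#'   irregular spacing are allowed.
#' @param a T x 3 matrix of accelerometer readings (units of g) in the raw
#'   sensor frame.
#' @param pulses Optional sync pulse times (s) shared with the LED clock.
#' @return An object of class `"accel_stream"`.
#' @export
accel_stream <- function(timestamps, a, pulses = numeric()) {
  a <- as.matrix(a)
  if (ncol(a) != 3) stop("a must have 3 columns (a_x, a_y, a_z)")
  if (nrow(a) != length(timestamps)) stop("timestamps/readings length mismatch")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, a = a, pulses = pulses),
            class = "accel_stream")
}

#' Calibrate the head-mounted accelerometer
#'
#' From a head-fixed calibration segment (enforced pitch = roll = 0),
#' computes the session-mean gravity vector, the calibration roll and
#' pitch angles `theta_r = arctan(a_y / a_z)` and
#' `theta_p = arctan(-a_x / sqrt(a_y^2 + a_z^2))`, and the frame rotation
#' `R_1to2 = (R_roll(theta_r) R_pitch(theta_p))^T` that maps raw readings
#' into the head frame in which the calibration gravity vector is
#' `(0, 0, 1)`.
#'
#' @param calibration_segment An [accel_stream()] covering >= 1 s of
#'   head-fixed data.
#' @return An object of class `"imu_calibration"` with elements
#'   `a_calib`, `theta_r`, `theta_p`, `R` (the 3x3 rotation),
#'   `n_roll`, `n_pitch`, and starting vector `s_start`.
#' @export
calibrate_imu <- function(calibration_segment) {
  stopifnot(inherits(calibration_segment, "accel_stream"))
  ts <- calibration_segment$timestamps
  if (diff(range(ts)) < 1) stop("calibration segment must cover >= 1 s")
  a <- colMeans(calibration_segment$a)
  if (sqrt(sum(a^2)) < 0.5) stop("calibration invalid: gravity norm < 0.5 g")
  theta_r <- atan2(a[2], a[3])
  theta_p <- atan(-a[1] / sqrt(a[2]^2 + a[3]^2))
  R <- t(rot_roll(theta_r) %*% rot_pitch(theta_p))
  structure(list(a_calib = a, theta_r = theta_r, theta_p = theta_p, R = R,
                 n_roll = c(0, 1, 0), n_pitch = c(1, 0, 0),
                 s_start = c(0, 0, 1)),
            class = "imu_calibration")
}

#' Head pitch and roll from a calibrated accelerometer stream
#'
#' Rotates each raw reading into the head frame, projects it onto the
#' pitch plane (normal `n_roll`) and the roll plane (normal `n_pitch`),
#' and takes the angle between the starting vector `(0,0,1)` and each
#' projection. The unsigned arccos is signed by the in-plane coordinate:
#' positive pitch = head up (`a_x > 0` in the head frame), positive
#' roll = rightward (ipsiversive) tilt (`a_y > 0`).
#'
#' @param stream An [accel_stream()].
#' @param calib An [imu_calibration()] from [calibrate_imu()].
#' @return List with numeric vectors `H_p` and `H_r` (degrees) and a
#'   logical `valid` mask (degenerate projections are masked).
#' @export
compute_pitch_roll <- function(stream, calib) {
  stopifnot(inherits(stream, "accel_stream"),
            inherits(calib, "imu_calibration"))
  a2 <- stream$a %*% t(calib$R)          # rows are a_C2
  s <- calib$s_start
  angle_in_plane <- function(a2, normal, sign_axis) {
    # proj_n(a) = a - (n^T a) n for unit normal n
    coef <- a2 %*% normal
    proj <- a2 - coef %*% t(normal)
    nrm <- sqrt(rowSums(proj^2))
    valid <- nrm > 1e-8
    cosang <- pmin(1, pmax(-1, (proj %*% s) / nrm))
    ang <- acos(cosang) * 180 / pi
    sgn <- sign(proj[, sign_axis])
    sgn[sgn == 0] <- 1
    list(angle = ifelse(valid, sgn * ang, NA_real_), valid = valid)
  }
  p <- angle_in_plane(a2, calib$n_roll, 1L)   # pitch: x-z plane, sign of a_x
  r <- angle_in_plane(a2, calib$n_pitch, 2L)  # roll:  y-z plane, sign of a_y
  list(H_p = p$angle, H_r = r$angle, valid = p$valid & r$valid)
}

#' Simulate a raw accelerometer stream for known head orientations
#'
#' Inverse of the pitch/roll recovery: for each commanded (pitch, roll)
#' pair the head-frame gravity vector is `normalize(tan p, tan r, 1)` and
#' the raw reading is obtained by rotating it back through the
#' calibration orientation. A head-fixed calibration segment
#' (pitch = roll = 0) is prepended. Gravity-only model: no translational
#' acceleration.
#'
#' @param pitch_series,roll_series Commanded angles in degrees,
#'   `|angle| < 90`.
#' @param calib_orientation Numeric `c(theta_r, theta_p)` in radians:
#'   mounting orientation of the sensor on the head.
#' @param sample_rate Stream sampling rate (Hz; default 30).
#' @param noise_sd Isotropic sensor noise SD in g (default 0).
#' @param drift Optional T x 3 matrix (or single vector) of additive slow
#'   drift in g.
#' @param calib_duration Length of the prepended calibration segment (s).
#' @param seed Optional seed for the sensor noise.
#' @return List with `stream` (the full [accel_stream()] including
#'   calibration), `calibration_segment` (an [accel_stream()]), and the
#'   ground-truth angle series.
#' @export
simulate_accelerometer <- function(pitch_series, roll_series,
                                   calib_orientation = c(0, 0),
                                   sample_rate = 30, noise_sd = 0,
                                   drift = NULL, calib_duration = 2,
                                   seed = NULL) {
  if (any(abs(pitch_series) >= 90) || any(abs(roll_series) >= 90))
    stop("gimbal-adjacent inputs (|angle| >= 90 deg) rejected")
  if (length(pitch_series) != length(roll_series))
    stop("pitch and roll series must have equal length")
  with_seed(seed, {
    th_r <- calib_orientation[1]; th_p <- calib_orientation[2]
    R21 <- rot_roll(th_r) %*% rot_pitch(th_p)    # head -> raw frame
    g2 <- cbind(tan(pitch_series * pi / 180), tan(roll_series * pi / 180), 1)
    g2 <- g2 / sqrt(rowSums(g2^2))
    a <- g2 %*% t(R21)
    n_cal <- max(2L, round(calib_duration * sample_rate))
    a_cal <- matrix(rep(as.numeric(R21 %*% c(0, 0, 1)), each = n_cal),
                    nrow = n_cal)
    n <- nrow(a)
    if (noise_sd > 0) {
      a <- a + matrix(stats::rnorm(3 * n, 0, noise_sd), ncol = 3)
      a_cal <- a_cal + matrix(stats::rnorm(3 * n_cal, 0, noise_sd), ncol = 3)
    }
    if (!is.null(drift)) {
      if (is.null(dim(drift))) drift <- matrix(drift, nrow = n, ncol = 3, byrow = TRUE)
      a <- a + drift
    }
    dt <- 1 / sample_rate
    t_cal <- seq(0, by = dt, length.out = n_cal)
    t_main <- max(t_cal) + dt + seq(0, by = dt, length.out = n)
    list(
      stream = accel_stream(t_main, a, pulses = t_main),
      calibration_segment = accel_stream(t_cal, a_cal),
      truth = list(H_p = pitch_series, H_r = roll_series)
    )
  })
}

#' Body position, speed and azimuth head direction from two LEDs
#'
#' Body position is the midpoint of the two headstage LEDs; body speed is
#' the Euclidean displacement per unit time; azimuth head direction is the
#' `atan2` of the LED difference vector (LED1 - LED2), counterclockwise
#' from the +x axis, mapped to `[0, 360)`.
#'
#' @param led1_xy,led2_xy T x 2 matrices of LED positions (cm) at the
#'   behavioral sampling rate. Rows with missing values are masked.
#' @param sample_rate Sampling rate (Hz; default 50).
#' @return List with `B_x`, `B_y`, `B_s`, `H_a` and a logical `valid`
#'   mask.
#' @export
compute_led_variables <- function(led1_xy, led2_xy, sample_rate = 50) {
  led1_xy <- as.matrix(led1_xy); led2_xy <- as.matrix(led2_xy)
  if (nrow(led1_xy) != nrow(led2_xy)) stop("LED tracks must have equal length")
  valid <- stats::complete.cases(led1_xy) & stats::complete.cases(led2_xy)
  bx <- (led1_xy[, 1] + led2_xy[, 1]) / 2
  by <- (led1_xy[, 2] + led2_xy[, 2]) / 2
  dt <- 1 / sample_rate
  bs <- c(0, sqrt(diff(bx)^2 + diff(by)^2)) / dt
  if (length(bs) > 1) bs[1] <- bs[2]
  dx <- led1_xy[, 1] - led2_xy[, 1]
  dy <- led1_xy[, 2] - led2_xy[, 2]
  ha <- wrap360(atan2(dy, dx) * 180 / pi)
  ha[dx == 0 & dy == 0] <- NA_real_
  list(B_x = bx, B_y = by, B_s = bs, H_a = ha,
       valid = valid & is.finite(ha))
}

#' Angular (or linear) velocity of a sampled angle series
#'
#' Finite difference over time; circular variables use the shortest
#' signed arc, so a 359 -> 1 degree step is +2 degrees, never -358.
#'
#' @param angle_series Angle series (degrees) at uniform sampling.
#' @param sample_rate Sampling rate (Hz).
#' @param circular Logical; wrap differences to `(-180, 180]`.
#' @return Velocity series (deg/s), same length (first sample repeated).
#' @export
compute_angular_velocities <- function(angle_series, sample_rate = 50,
                                       circular = FALSE) {
  deriv_series(angle_series, 1 / sample_rate, circular = circular)
}

#' Synchronize IMU-derived channels with the LED clock and bin spikes
#'
#' IMU channels are linearly interpolated onto the uniform 50 Hz LED
#' clock after aligning the two clocks through their shared sync pulses
#' (a linear map fitted to matched pulse times). Spike event times are
#' binned into half-open 20 ms bins `[t, t + dt)` aligned to the same
#' clock.
#'
#' @param led_time Uniform behavioral clock (s).
#' @param imu_time,imu_channels IMU sample times and a named list of
#'   channels sampled at those times.
#' @param spikes Numeric vector of spike event times (s, behavioral
#'   clock), or a list of such vectors (one per cell).
#' @param led_pulses,imu_pulses Matched sync pulse times recorded in each
#'   datastream; equal counts required.
#' @return List with `channels` (interpolated onto `led_time`) and
#'   `counts` (integer vector or matrix of spike counts per 20 ms bin).
#' @export
synchronize_and_bin <- function(led_time, imu_time, imu_channels,
                                spikes, led_pulses = NULL,
                                imu_pulses = NULL) {
  if (!is.null(led_pulses) || !is.null(imu_pulses)) {
    if (length(led_pulses) != length(imu_pulses))
      stop("synchronization failure: unmatched pulse counts")
    if (length(led_pulses) >= 2) {
      fit <- stats::lm.fit(cbind(1, imu_pulses), led_pulses)
      imu_time <- fit$coefficients[1] + fit$coefficients[2] * imu_time
    } else if (length(led_pulses) == 1) {
      imu_time <- imu_time + (led_pulses - imu_pulses)
    }
  }
  channels <- lapply(imu_channels, function(ch)
    stats::approx(imu_time, ch, xout = led_time, rule = 2)$y)
  dt <- 0.02
  t0 <- led_time[1]
  n_bins <- length(led_time)
  bin_one <- function(ev) {
    ev <- ev[ev >= t0 & ev < t0 + n_bins * dt]
    idx <- floor((ev - t0) / dt)
    as.integer(tabulate(idx + 1L, nbins = n_bins))
  }
  counts <- if (is.list(spikes)) {
    m <- vapply(spikes, bin_one, integer(n_bins))
    colnames(m) <- names(spikes)
    m
  } else bin_one(spikes)
  list(channels = channels, counts = counts)
}
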