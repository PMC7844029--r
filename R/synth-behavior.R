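#' Specification of a synthetic behavior session
#'
#' Collects arena geometry, session length, per-variable stochastic-process
#' parameters and the seed that fully determines the generated session.
#' Head-orientation and eye traces are mean-reverting (discretized
#' Ornstein-Uhlenbeck) processes; azimuth is a circular random walk driven
#' by a regime-switching (slow/fast) velocity process whose stationary
#' marginal is a two-component Gaussian scale mixture; eye traces add
#' saccade-like jump excursions to produce heavy tails. Default process
#' parameters are calibrated so that the marginal percentiles of pitch,
#' roll, azimuthal head velocity and eye position match the published
#' across-mouse values for freely foraging and head-fixed mice.
#'
#' @param kind `"open_field"` or `"vr_track"`.
#' @param session_length Session duration in seconds (>= 60 s for any
#'   model-fitting use).
#' @param sample_rate Behavioral sampling rate in Hz (default 50).
#' @param width,height Open-field arena size in cm.
#' @param track_length,n_landmarks Virtual track length (cm) and number of
#'   evenly spaced landmarks.
#' @param processes Named list of per-variable process parameters; entries
#'   override the calibrated defaults (see Details in the vignette).
#' @param seed Integer seed; identical (spec, seed) pairs give
#'   bit-identical sessions.
#' @return An object of class `"behavior_spec"`.
#' @export
behavior_spec <- function(kind = c("open_field", "vr_track"),
                          session_length = 1200, sample_rate = 50,
                          width = 50, height = 50,
                          track_length = 400, n_landmarks = 5,
                          processes = list(), seed = 1) {
  kind <- match.arg(kind)
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (session_length <= 0) stop("session_length must be positive")
  if (kind == "open_field" && (width <= 0 || height <= 0))
    stop("arena dimensions must be positive")
  if (kind == "vr_track" && track_length <= 0)
    stop("track length must be positive")
  def <- list(
    pitch  = list(mean = 11.5, sd = 20,  tau = 0.6, smooth_sigma = 2),
    roll   = list(mean = -0.8, sd = 26,  tau = 0.6, smooth_sigma = 2),
    azimuth_velocity = list(sd_slow = 45, sd_fast = 400, p_fast = 0.15,
                            dur_fast = 0.2, tau = 0.1),
    velocity = list(sd = 9, tau = 0.7),          # open-field body velocity/axis
    run_speed = list(mean = 20, sd = 12, tau = 2),  # VR wheel speed
    eye_h = list(mean = -0.11, sd = 1.0, tau = 8,
                 jump_rate = 0.5, jump_pos_mean = 2.2, jump_neg_mean = 1.3,
                 p_pos = 0.55, jump_tau = 0.5),
    eye_v = list(mean = -0.035, sd = 0.33, tau = 6,
                 jump_rate = 0.35, jump_pos_mean = 1.0, jump_neg_mean = 1.1,
                 p_pos = 0.5, jump_tau = 0.5)
  )
  for (nm in names(processes)) def[[nm]] <- utils::modifyList(def[[nm]] %||% list(), processes[[nm]])
  structure(list(kind = kind, session_length = session_length,
                 sample_rate = sample_rate, width = width, height = height,
                 track_length = track_length, n_landmarks = n_landmarks,
                 processes = def, seed = seed),
            class = "behavior_spec")
}

#' Construct a behavior session container
#'
#' A uniformly sampled multichannel behavior time series with a per-channel
#' validity mask; the regressor source for the LN model.
#'
#' @param time Uniform timestamp vector (s).
#' @param channels Named list of numeric channels, all the same length as
#'   `time`. Azimuth (`H_a`) must lie in `[0, 360)`.
#' @param mask Optional named list of logical vectors (TRUE = valid);
#'   missing entries default to all-valid.
#' @param sample_rate Sampling rate (Hz).
#' @param arena List describing the arena, e.g.
#'   `list(kind = "open_field", width = 50, height = 50)` or
#'   `list(kind = "vr_track", length = 400, n_landmarks = 5)`.
#' @return An object of class `"behavior_session"`.
#' @export
behavior_session <- function(time, channels, mask = list(),
                             sample_rate, arena) {
  len <- vapply(channels, length, integer(1))
  if (any(len != length(time))) stop("all channels must match time length")
  full_mask <- lapply(channels, function(ch) rep(TRUE, length(time)))
  for (nm in names(mask)) {
    if (length(mask[[nm]]) != length(time)) stop("mask length mismatch: ", nm)
    full_mask[[nm]] <- mask[[nm]]
  }
  if ("H_a" %in% names(channels)) {
    ha <- channels$H_a[full_mask$H_a & is.finite(channels$H_a)]
    if (length(ha) && (min(ha) < 0 || max(ha) >= 360))
      stop("H_a must lie in [0, 360)")
  }
  structure(list(time = time, channels = channels, mask = full_mask,
                 sample_rate = sample_rate, arena = arena),
            class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  cat(sprintf("<behavior_session> %s, %.1f s at %g Hz, %d channels\n",
              x$arena$kind, diff(range(x$time)) + 1 / x$sample_rate,
              x$sample_rate, length(x$channels)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.behavior_session <- function(x, ...) {
  df <- data.frame(time = x$time)
  for (nm in names(x$channels)) df[[nm]] <- x$channels[[nm]]
  df
}

# OU trace, lightly smoothed, then affinely matched to the target
# mean/sd (the calibration contract of the generator).
calibrated_ou <- function(n, dt, p) {
  x <- ou_process(n, dt, mean = p$mean, sd = p$sd, tau = p$tau)
  if (p$sd <= 0) return(x)
  if (!is.null(p$smooth_sigma) && p$smooth_sigma > 0)
    x <- gauss_smooth(x, p$smooth_sigma)
  s <- stats::sd(x)
  if (s > 0) x <- p$mean + (x - mean(x)) * (p$sd / s)
  x
}

# Regime-switching angular velocity: two-state Markov chain (slow/fast)
# scaling a unit-variance AR(1); marginal is the Gaussian scale mixture
# p_fast * N(0, sd_fast^2) + (1 - p_fast) * N(0, sd_slow^2).
switching_velocity <- function(n, dt, p) {
  if (p$sd_slow <= 0 && p$sd_fast <= 0) return(numeric(n))
  b <- dt / p$dur_fast                       # fast -> slow exit prob
  a <- b * p$p_fast / (1 - p$p_fast)         # slow -> fast entry prob
  state <- logical(n)                        # TRUE = fast
  state[1] <- stats::runif(1) < p$p_fast
  u <- stats::runif(n - 1)
  for (t in seq_len(n - 1L))
    state[t + 1L] <- if (state[t]) u[t] >= b else u[t] < a
  phi <- exp(-dt / p$tau)
  z <- ou_process(n, dt, mean = 0, sd = 1, tau = p$tau)
  ifelse(state, p$sd_fast, p$sd_slow) * z
}

# Mean-reverting base + saccade-like exponentially decaying jump pulses.
# The sample median is anchored to p$mean (the printed median is the
# calibration target of the generator).
jumpy_trace <- function(n, dt, p) {
  base <- ou_process(n, dt, mean = p$mean, sd = p$sd, tau = p$tau)
  n_ev <- stats::rpois(1, p$jump_rate * n * dt)
  pulse <- numeric(n)
  if (n_ev > 0) {
    at <- sample.int(n, n_ev, replace = TRUE)
    pos <- stats::runif(n_ev) < p$p_pos
    amp <- ifelse(pos, stats::rexp(n_ev, 1 / p$jump_pos_mean),
                  -stats::rexp(n_ev, 1 / p$jump_neg_mean))
    decay <- exp(-(0:ceiling(6 * p$jump_tau / dt)) * dt / p$jump_tau)
    for (k in seq_len(n_ev)) {
      idx <- at[k]:min(n, at[k] + length(decay) - 1L)
      pulse[idx] <- pulse[idx] + amp[k] * decay[seq_along(idx)]
    }
  }
  x <- base + pulse
  if (p$sd > 0) x <- x + (p$mean - stats::median(x))
  x
}

#' Simulate open-field foraging behavior
#'
#' Generates a 50 Hz session of body position (reflected random walk
#' inside the arena), body speed, azimuth head direction (circular random
#' walk), head pitch and roll (mean-reverting processes) and the three
#' angular velocities (finite differences). Default process parameters
#' reproduce the published across-mouse pitch/roll/azimuthal-velocity
#' percentiles within their reported uncertainty.
#'
#' @param spec A [behavior_spec()] with `kind = "open_field"`.
#' @return A [behavior_session()] with channels
#'   `B_x, B_y, B_s, H_a, H_p, H_r, dH_a, dH_p, dH_r`.
#' @export
simulate_open_field_behavior <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  if (spec$kind != "open_field") stop("spec$kind must be 'open_field'")
  dt <- 1 / spec$sample_rate
  n <- round(spec$session_length * spec$sample_rate)
  if (n < 50) stop("session too short to estimate percentiles")
  with_seed(spec$seed, {
    p <- spec$processes
    pitch <- calibrated_ou(n, dt, p$pitch)
    roll <- calibrated_ou(n, dt, p$roll)
    omega <- switching_velocity(n, dt, p$azimuth_velocity)
    ha <- wrap360(cumsum(omega) * dt + stats::runif(1, 0, 360))
    vx <- ou_process(n, dt, 0, p$velocity$sd, p$velocity$tau)
    vy <- ou_process(n, dt, 0, p$velocity$sd, p$velocity$tau)
    x <- reflect_walk(cumsum(vx) * dt + stats::runif(1, 0, spec$width), spec$width)
    y <- reflect_walk(cumsum(vy) * dt + stats::runif(1, 0, spec$height), spec$height)
    bs <- c(0, sqrt(diff(x)^2 + diff(y)^2)) / dt
    bs[1] <- bs[2]
    ch <- list(
      B_x = x, B_y = y, B_s = bs, H_a = ha, H_p = pitch, H_r = roll,
      dH_a = deriv_series(ha, dt, circular = TRUE),
      dH_p = deriv_series(pitch, dt), dH_r = deriv_series(roll, dt)
    )
    behavior_session(seq(0, by = dt, length.out = n), ch,
                     sample_rate = spec$sample_rate,
                     arena = list(kind = "open_field", width = spec$width,
                                  height = spec$height))
  })
}

# fold an unbounded coordinate into [0, L] by reflection
reflect_walk <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

# finite-difference derivative; first sample repeats the second
deriv_series <- function(x, dt, circular = FALSE) {
  d <- if (circular) ang_diff(x[-1], x[-length(x)]) else diff(x)
  v <- c(0, d) / dt
  v[1] <- v[2]
  v
}

#' Simulate head-fixed virtual-track behavior
#'
#' Generates running along a circular virtual linear track (position wraps
#' at the track length) plus horizontal and vertical eye position traces
#' with saccade-like heavy-tailed excursions, in units of % of eye width.
#' Eye velocities are smoothed finite differences (Gaussian, sigma 140 ms),
#' matching the measurement pipeline applied to recorded eyes.
#'
#' @param spec A [behavior_spec()] with `kind = "vr_track"`.
#' @return A [behavior_session()] with channels
#'   `B, B_s, E_h, E_v, dE_h, dE_v`.
#' @export
simulate_vr_behavior <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  if (spec$kind != "vr_track") stop("spec$kind must be 'vr_track'")
  dt <- 1 / spec$sample_rate
  n <- round(spec$session_length * spec$sample_rate)
  if (n < 50) stop("session too short to estimate percentiles")
  with_seed(spec$seed, {
    p <- spec$processes
    speed <- pmax(0, ou_process(n, dt, p$run_speed$mean, p$run_speed$sd,
                                p$run_speed$tau))
    pos <- (cumsum(speed) * dt) %% spec$track_length
    eh <- jumpy_trace(n, dt, p$eye_h)
    ev <- jumpy_trace(n, dt, p$eye_v)
    sm <- function(e) smooth_and_differentiate(e, spec$sample_rate)
    seh <- sm(eh); sev <- sm(ev)
    ch <- list(B = pos, B_s = speed,
               E_h = seh$position, E_v = sev$position,
               dE_h = seh$velocity, dE_v = sev$velocity)
    behavior_session(seq(0, by = dt, length.out = n), ch,
                     sample_rate = spec$sample_rate,
                     arena = list(kind = "vr_track", length = spec$track_length,
                                  n_landmarks = spec$n_landmarks))
  })
}

#' Fraction of position bins visited
#'
#' Coverage of the arena on the model's position grid (open field:
#' `round(cm * 15/100)` bins per axis; virtual track: 20 bins). Sessions
#' with < 70% coverage are conventionally excluded from model fitting.
#'
#' @param session A [behavior_session()].
#' @return Fraction of position bins visited, in `[0, 1]`.
#' @export
position_coverage <- function(session) {
  a <- session$arena
  if (identical(a$kind, "open_field")) {
    nx <- max(4L, round(a$width * 15 / 100))
    ny <- max(4L, round(a$height * 15 / 100))
    ix <- pmin(nx, pmax(1L, ceiling(session$channels$B_x / a$width * nx)))
    iy <- pmin(ny, pmax(1L, ceiling(session$channels$B_y / a$height * ny)))
    length(unique((ix - 1L) * ny + iy)) / (nx * ny)
  } else {
    ib <- pmin(20L, pmax(1L, ceiling(session$channels$B / a$length * 20)))
    length(unique(ib)) / 20
  }
}
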