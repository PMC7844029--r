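test_that("pupil detection finds the disk center within half a pixel", {
  fr <- simulate_eye_frames(cbind(40, 30),
                            geometry = list(width = 80, height = 60,
                                            pupil_radius = 10))
  dp <- detect_pupil(fr$frames[[1]], 80)
  expect_true(dp$valid)
  expect_lt(abs(dp$cx - 40), 0.5)
  expect_lt(abs(dp$cy - 30), 0.5)
  expect_true(dp$n_pixels > 50 && dp$n_pixels < 1000)
  expect_equal(dp$r, 10, tolerance = 0.5)
})

test_that("the connected-pixel count window invalidates frames", {
  # a ~30 px disk (radius 3) is below the 50-px bound
  small <- matrix(128, 60, 80)
  xs <- matrix(rep(1:80, each = 60), 60); ys <- matrix(rep(1:60, 80), 60)
  small[(xs - 40)^2 + (ys - 30)^2 <= 9] <- 20
  expect_false(detect_pupil(small, 80)$valid)
  # a huge dark region exceeds the 1000-px bound
  big <- matrix(128, 60, 80); big[10:50, 10:60] <- 20
  expect_false(detect_pupil(big, 80)$valid)
  # uniform frame: no component at all
  expect_false(detect_pupil(matrix(128, 60, 80), 80)$valid)
  expect_false(detect_cr(matrix(128, 60, 80), 200)$valid)
})

test_that("search regions restrict detection to the expected area", {
  fr <- simulate_eye_frames(cbind(60, 40))$frames[[1]]
  hit <- detect_pupil(fr, 80, search_region = c(45, 80, 25, 60))
  miss <- detect_pupil(fr, 80, search_region = c(1, 30, 1, 20))
  expect_true(hit$valid)
  expect_false(miss$valid)
})

test_that("CR referencing cancels rigid camera jitter", {
  set.seed(14)
  n <- 1200
  trace <- cbind(40 + 6 * sin(seq_len(n) / 30), 30 + 4 * cos(seq_len(n) / 40))
  fr <- simulate_eye_frames(trace, jitter_sd = 1.5, seed = 3)
  tk <- track_frames(fr$frames)
  ax <- eye_axes(c(5, 30), c(75, 30))
  es <- build_eye_timeseries(tk$pupil_xy, tk$cr_xy, ax)
  # jitter moves pupil and CR together: CR-referenced horizontal position
  # recovers the commanded oscillation
  truth <- (trace[, 1] - mean(trace[, 1])) / ax$width * 100
  ok <- es$valid
  expect_gt(cor(es$E_h[ok], truth[ok]), 0.98)
  # per-frame jitter must not leak through at its raw amplitude
  resid <- es$E_h[ok] - truth[ok]
  expect_lt(sd(resid), sd(fr$jitter[, 1]) / ax$width * 100 / 2)
})

test_that("drift removal attenuates slow camera drift but keeps signal", {
  n <- 3000
  osc <- 5 * sin(2 * pi * seq_len(n) / 50)     # fast oscillation
  drift <- seq(0, 20, length.out = n)          # slow linear drift
  pupil <- cbind(40 + osc + drift, rep(30, n))
  cr <- cbind(rep(20, n), rep(15, n))
  ax <- eye_axes(c(0, 30), c(70, 30))
  es <- build_eye_timeseries(pupil, cr, ax)
  ok <- es$valid & seq_len(n) > 500 & seq_len(n) < n - 500
  sig <- es$E_h[ok] * ax$width / 100
  # oscillation amplitude preserved, drift attenuated more than 10-fold
  expect_gt(sd(sig), 0.8 * sd(osc))
  expect_lt(abs(coef(lm(sig ~ seq_along(sig)))[2]) * n,
            (20 / 10))
  # a constant pupil position maps to zero after drift removal
  es0 <- build_eye_timeseries(cbind(rep(40, 1500), rep(30, 1500)),
                              cbind(rep(20, 1500), rep(15, 1500)), ax)
  expect_equal(max(abs(es0$E_h[es0$valid])), 0, tolerance = 1e-9)
})

test_that("extremal masking removes the stated 2% per coordinate", {
  set.seed(15)
  n <- 5000
  pupil <- cbind(40 + rnorm(n), 30 + rnorm(n))
  cr <- cbind(rep(20, n), rep(15, n))
  es <- build_eye_timeseries(pupil, cr, eye_axes(c(0, 30), c(70, 30)))
  drop_frac <- mean(!es$valid)
  expect_gte(drop_frac, 0.02)        # two coordinates, 2% each, overlapping
  expect_lte(drop_frac, 0.045)
})

test_that("projection and normalization follow the eye axes", {
  ax <- eye_axes(c(10, 20), c(60, 20))   # width 50, horizontal = +x
  expect_equal(ax$width, 50)
  n <- 1200
  # fast square wave along the horizontal axis with 2%-of-eye-width
  # amplitude: well inside the passband of the 1000-point drift filter
  blocks <- rep(rep(1:2, each = 25), length.out = n)
  pupil <- cbind(40 + (blocks - 1) * 0.02 * ax$width, rep(30, n))
  cr <- cbind(rep(20, n), rep(15, n))
  es <- build_eye_timeseries(pupil, cr, ax, drift_window = 1000)
  lvl <- diff(tapply(es$E_h[es$valid], blocks[es$valid], median))
  expect_equal(unname(lvl), 2, tolerance = 0.05)
  expect_lt(max(abs(es$E_v[es$valid])), 0.05)
  # units scale inversely with eye width
  ax2 <- eye_axes(c(10, 20), c(110, 20))  # doubled width
  es2 <- build_eye_timeseries(pupil, cr, ax2, drift_window = 1000)
  lvl2 <- diff(tapply(es2$E_h[es2$valid], blocks[es2$valid], median))
  expect_equal(unname(lvl2), 1, tolerance = 0.05)
})

test_that("sessions with too many invalid frames are rejected", {
  pupil <- cbind(rep(40, 1200), rep(30, 1200))
  pupil[1:400, ] <- NA
  cr <- cbind(rep(20, 1200), rep(15, 1200))
  expect_error(build_eye_timeseries(pupil, cr, eye_axes(c(0, 30), c(70, 30))),
               "rejected")
})

test_that("smoothing and differentiation behave on analytic inputs", {
  const <- smooth_and_differentiate(rep(3, 500), 50)
  expect_equal(const$velocity, rep(0, 500), tolerance = 1e-12)
  t <- seq(0, 10, by = 0.02)
  ramp <- smooth_and_differentiate(1 * t, 50)
  mid <- 100:400
  expect_equal(ramp$velocity[mid], rep(1, length(mid)), tolerance = 1e-6)
  # Gaussian kernel positivity: a smoothed step never overshoots
  step <- smooth_and_differentiate(rep(c(0, 1), each = 250), 50)
  expect_true(all(step$position >= 0 - 1e-12 & step$position <= 1 + 1e-12))
})

test_that("frame stacks round-trip through PNG", {
  fr <- simulate_eye_frames(cbind(c(40, 42), c(30, 31)))
  dir <- tempfile()
  write_frames_png(fr$frames, dir)
  back <- read_frames_png(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]], fr$frames[[1]], tolerance = 0.5)
  unlink(dir, recursive = TRUE)
})

test_that("static traces give identical frames and radii out of range error", {
  fr <- simulate_eye_frames(cbind(c(40, 40), c(30, 30)))
  expect_identical(fr$frames[[1]], fr$frames[[2]])
  expect_error(simulate_eye_frames(cbind(40, 30),
                                   geometry = list(pupil_radius = 3)),
               "pixel-count window")
  expect_error(simulate_eye_frames(cbind(200, 30)), "outside frame")
})
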