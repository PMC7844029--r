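test_that("model-derived curves reduce to the mean rate for zero weights", {
  ses <- fx_vr_session()
  des <- fx_vr_design()
  set.seed(41)
  y <- rpois(nrow(des$X), 0.15)
  fit <- ln_fit(des, y, "E_h")
  # force zero weights: the curve must be flat at exp(b0)/dt
  fit$w$E_h[] <- 0
  fit$coef_vector[-1] <- 0
  tc <- model_tuning_curve(fit, "E_h")
  expect_equal(range(tc$rate), rep(exp(fit$b0) / 0.02, 2), tolerance = 1e-10)
})

test_that("the scaling gamma is exp(b0) for single-variable fits", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(E_h = tuning_poly(c(0.8, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 42)
  fit <- ln_fit(fx_vr_design(), y, "E_h")
  tc <- model_tuning_curve(fit, "E_h")
  k <- fit$design$knots$E_h
  Y <- lnspike:::spline_design_1d(tc$centers, k, s = 0.6)
  manual <- as.numeric(exp(Y %*% fit$w$E_h)) * exp(fit$b0) / 0.02
  expect_equal(tc$rate, manual, tolerance = 1e-12)
})

test_that("Eq-10 normalization: occupancy-weighted curve mean equals mean rate", {
  ses <- simulate_vr_behavior(behavior_spec("vr_track", 1200, seed = 53))
  cell <- ground_truth_cell(log(0.1),
                            list(B = tuning_place1d(150, 35, 2),
                                 E_h = tuning_poly(c(0.9, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 43)
  des <- assemble_design(ses, default_variable_configs(ses))
  fit <- ln_fit(des, y, c("B", "E_h"))
  tc <- model_tuning_curve(fit, "E_h")
  vals <- ses$channels$E_h[des$retained]
  keep <- vals >= tc$range[1] & vals <= tc$range[2]
  occ_mean <- mean(approx(tc$centers, tc$rate, xout = vals[keep], rule = 2)$y)
  obs_rate <- mean(y[des$retained][keep]) / 0.02
  expect_lt(abs(occ_mean - obs_rate) / obs_rate, 0.05)
})

test_that("raw tuning curves are spikes over occupancy", {
  # constructed micro-session: 2 spikes in 0.5 s of occupancy -> 4 spikes/s
  n <- 1500
  b <- c(rep(2, 25), rep(95, n - 25))        # 0.5 s in the first bin
  ses <- behavior_session(seq(0, by = 0.02, length.out = n),
                          list(B = b, B_s = rep(10, n)),
                          sample_rate = 50,
                          arena = list(kind = "vr_track", length = 100,
                                       n_landmarks = 0))
  y <- integer(n); y[c(3, 17)] <- 1L
  rc <- raw_tuning_curve(ses, y, "B", smooth = FALSE)
  expect_equal(rc$rate[1], 2 / 0.5)
  expect_equal(rc$occupancy[1], 0.5)
  # unvisited bins are NA, never interpolated
  expect_true(any(is.na(rc$rate)))
})

test_that("raw curves are flat for homogeneous Poisson spiking", {
  ses <- fx_vr_session()
  set.seed(44)
  y <- rpois(length(ses$time), 0.2)
  rc <- raw_tuning_curve(ses, y, "E_h")
  expect_lt(diff(range(rc$rate, na.rm = TRUE)), 0.25 * 0.2 / 0.02)
})

test_that("model and raw curves agree on simulated data", {
  ses <- simulate_vr_behavior(behavior_spec("vr_track", 1200, seed = 54))
  cell <- ground_truth_cell(log(0.1), list(E_h = tuning_poly(c(1.0, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 45)
  fit <- ln_fit(ses, y, "E_h")
  tc <- model_tuning_curve(fit, "E_h")
  rc <- raw_tuning_curve(ses, y, "E_h")
  m_on_raw <- approx(tc$centers, tc$rate, xout = rc$centers, rule = 2)$y
  expect_gt(cor(m_on_raw, rc$rate, use = "complete.obs"), 0.9)
})

test_that("stability is one for duplicated halves and negative for flips", {
  ses <- fx_vr_session()
  n <- length(ses$time)
  half <- lnspike:::subset_session(ses, 1:(n %/% 2))
  dup <- behavior_session(seq(0, by = 0.02, length.out = 2 * (n %/% 2)),
                          lapply(half$channels, rep, times = 2),
                          sample_rate = 50, arena = ses$arena)
  cell <- ground_truth_cell(log(0.12), list(E_h = tuning_poly(c(0.9, 0), c(-3, 3))))
  yh <- generate_ln_spikes(cell, half, seed = 46)
  st <- tuning_stability(dup, rep(yh, 2), "E_h", "E_h")
  expect_equal(st, 1, tolerance = 1e-6)
  # adversarial: tuning sign flips between halves
  flip <- ground_truth_cell(log(0.12), list(E_h = tuning_poly(c(-0.9, 0), c(-3, 3))))
  yf <- generate_ln_spikes(flip, half, seed = 47)
  st2 <- tuning_stability(dup, c(yh, yf), "E_h", "E_h")
  expect_lt(st2, 0)
})

test_that("stationary tuning is highly stable across halves", {
  ses <- simulate_vr_behavior(behavior_spec("vr_track", 1200, seed = 55))
  cell <- ground_truth_cell(log(0.1), list(E_h = tuning_poly(c(1.0, 0.2), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 48)
  expect_gt(tuning_stability(ses, y, "E_h", "E_h"), 0.9)
})

test_that("polynomial shape classification finds the generative degree", {
  g <- seq(-3, 3, length.out = 200)
  # exact line: degree 1 with all error explained
  lin <- classify_shape(make_curve("E_h", g, 5 + 2 * g))
  expect_equal(lin$degree, 1L)
  expect_equal(lin$fraction, 1)
  # quadratic plus 1% noise
  set.seed(49)
  yq <- (g / 3)^2
  q <- classify_shape(make_curve("E_h", g, yq + rnorm(200, 0, 0.01 * diff(range(yq)))))
  expect_equal(q$degree, 2L)
  # Legendre fixtures genuinely need degrees 1..5
  for (d in 1:5) {
    crv <- make_curve("E_h", g, 10 + 4 * legendre[[d]](g / 3))
    expect_equal(classify_shape(crv)$degree, d)
  }
})

test_that("white-noise curves are usually unclassified at the 0.9 bar", {
  set.seed(50)
  g <- seq(-3, 3, length.out = 200)
  degs <- replicate(100, classify_shape(make_curve("E_h", g, rnorm(200)))$degree)
  expect_gt(mean(is.na(degs)), 0.8)
})

test_that("shape classification is invariant to scale and offset", {
  set.seed(51)
  g <- seq(-3, 3, length.out = 200)
  y <- (g / 3)^2 + rnorm(200, 0, 0.02)
  a <- classify_shape(make_curve("E_h", g, y))
  b <- classify_shape(make_curve("E_h", g, 7 + 40 * y))
  expect_equal(a$degree, b$degree)
  expect_equal(a$fraction, b$fraction, tolerance = 1e-12)
})

test_that("coverage and degeneracy rules withhold classification", {
  g <- seq(-0.5, 0.5, length.out = 50)   # 10% of the eye preset range
  out <- classify_shape(make_curve("E_h", g, g^2))
  expect_false(out$coverage_ok)
  expect_true(is.na(out$degree))
  flat <- classify_shape(make_curve("E_h", seq(-3, 3, length.out = 50),
                                    rep(2, 50)))
  expect_true(is.na(flat$degree))
})

test_that("velocity subtypes are recovered on parametric fixtures", {
  g <- seq(-3, 3, length.out = 200)
  expect_equal(classify_velocity_subtype(make_curve("dE_h", g, 5 + 1.2 * g))$subtype,
               "L_as")
  v <- classify_velocity_subtype(make_curve("dE_h", g, 5 + 2 * abs(g)))
  expect_equal(v$subtype, "NL_s-pos")
  expect_equal(v$preferred, g[which.min(abs(g))], tolerance = 0.05)
  iv <- classify_velocity_subtype(make_curve("dE_h", g, 10 - 2 * abs(g)))
  expect_equal(iv$subtype, "NL_s-neg")
  hr <- classify_velocity_subtype(make_curve("dE_h", g, 5 + 2 * pmax(0, g)))
  expect_equal(hr$subtype, "NL_as")
  expect_equal(hr$direction, "positive")
  expect_error(classify_velocity_subtype(make_curve("dE_h", g + 10, g)),
               "zero inside")
})

test_that("variable contributions reflect the generative weights", {
  ses <- simulate_vr_behavior(behavior_spec("vr_track", 1200, seed = 56))
  cell <- ground_truth_cell(log(0.1),
                            list(B = tuning_place1d(150, 35, 2.2),
                                 E_h = tuning_poly(c(0.7, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 57)
  sel <- forward_select(ses, y)
  expect_setequal(sel$selected, c("B", "E_h"))
  cb <- variable_contribution(sel, "B")
  ce <- variable_contribution(sel, "E_h")
  # the dominant variable contributes most, and both are positive
  expect_gt(cb$contribution, ce$contribution)
  expect_gt(cb$contribution, 0)
  expect_gt(ce$contribution, 0)
  expect_true(is.finite(cb$correlation_delta))
  # single-variable models are excluded by contract
  expect_error(variable_contribution(
    structure(list(selected = "B"), class = "ln_select"), "B"),
    "at least one other")
})
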