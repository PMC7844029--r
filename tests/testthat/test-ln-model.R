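test_that("design assembly enforces windows, masks and partition of unity", {
  ses <- fx_vr_session()
  des <- fx_vr_design()
  # every retained sample lies inside every variable's window
  for (sym in names(des$cols)) {
    cfg <- des$configs[[sym]]
    if (cfg$circular) next
    k <- des$knots[[sym]]
    v <- ses$channels[[sym]][des$retained]
    expect_true(all(v >= k[1] & v <= k[length(k)]), label = sym)
    # and each block row sums to one
    Xi <- des$X[, des$cols[[sym]], drop = FALSE]
    expect_lt(max(abs(Matrix::rowSums(Xi) - 1)), 1e-10)
  }
  # the circular track-position block too
  Xb <- des$X[, des$cols$B, drop = FALSE]
  expect_lt(max(abs(Matrix::rowSums(Xb) - 1)), 1e-10)
  expect_error(assemble_design(lnspike:::subset_session(ses, 1:300),
                               default_variable_configs(ses)),
               "insufficient data")
})

test_that("the mean-rate model recovers log(mean count) exactly", {
  set.seed(31)
  y <- rpois(5000, 0.3)
  des <- fx_vr_design()
  fit <- ln_fit(des, rep(y, length.out = nrow(des$X)), character(0))
  expect_equal(fit$b0, log(mean(rep(y, length.out = nrow(des$X)))))
})

test_that("a constant weight vector yields a constant rate contribution", {
  des <- fx_vr_design()
  Xb <- des$X[, des$cols$B, drop = FALSE]
  contrib <- exp(as.numeric(Xb %*% rep(0.7, ncol(Xb))))
  expect_equal(range(contrib), rep(exp(0.7), 2), tolerance = 1e-10)
})

test_that("doubling the penalty shrinks the weights monotonically", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(E_h = tuning_poly(c(0.8, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 12)
  des <- fx_vr_design()
  norms <- vapply(c(1, 2, 4, 8), function(b)
    sqrt(sum(unlist(ln_fit(des, y, "E_h", beta = b)$w)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("the optimizer reaches tight gradient norms on concave problems", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(B = tuning_place1d(100, 30, 2)))
  y <- generate_ln_spikes(cell, ses, seed = 13)
  fit <- ln_fit(fx_vr_design(), y, c("B", "E_h"))
  expect_true(fit$converged)
  expect_lt(fit$grad_max, 1e-6)
})

test_that("penalized fit agrees with an independent ridge-Poisson solver", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 4000
  x <- runif(n, -1, 1)
  k <- seq(-1, 1, length.out = 5)
  X <- lnspike:::spline_design_1d(x, k, s = 0.6)
  eta <- 0.5 * x + log(0.2)
  y <- rpois(n, exp(eta))
  res <- lnspike:::fit_penalized_poisson(X, y, beta = 1)
  gl <- glmnet::glmnet(as.matrix(X), y, family = "poisson", alpha = 0,
                       lambda = 2 * 1 / n, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(res$coef[1], as.numeric(gl$a0), tolerance = 1e-3)
  expect_equal(res$coef[-1], as.numeric(gl$beta), tolerance = 5e-3)
})

test_that("single-variable tuning is reconstructed from simulated spikes", {
  ses <- simulate_vr_behavior(behavior_spec("vr_track", 1200, seed = 52))
  cell <- ground_truth_cell(log(0.1),
                            list(E_h = tuning_poly(c(1.0, 0.3), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 14)
  fit <- ln_fit(ses, y, "E_h")
  tc <- model_tuning_curve(fit, "E_h")
  truth <- exp(log(0.1) + evaluate_tuning(cell$tuning$E_h, tc$centers)) / 0.02
  # reconstructed curve within 10% of ground truth across bins
  expect_lt(max(abs(tc$rate - truth) / truth), 0.1)
  expect_gt(cor(tc$rate, truth), 0.99)
})

test_that("cross-validation folds partition the retained data by 10-s sections", {
  des <- fx_vr_design()
  expect_setequal(unique(des$fold), 1:10)
  # fold labels are constant within each 10-s section and cycle round-robin
  sec <- floor(des$time / 10)
  expect_true(all(tapply(des$fold, sec, function(f) length(unique(f))) == 1))
  expect_equal(as.integer(tapply(des$fold, sec, unique)),
               as.integer(sort(unique(sec)) %% 10 + 1))
})

test_that("held-out LLI is centered near zero for mean-rate data", {
  des <- fx_vr_design()
  set.seed(35)
  y <- rpois(nrow(des$X), 0.12)
  cv <- crossvalidate(des, y, "E_h")
  se <- sd(cv$lli) / sqrt(length(cv$lli))
  # the penalized 5-parameter model carries a small negative held-out
  # bias relative to the true (flat) model; ~1 nat against ~3600 spikes
  expect_lt(abs(mean(cv$lli)), max(2.5 * se, 1))
  # and the bias-only model scores exactly zero by construction
  cv0 <- crossvalidate(des, y, character(0))
  expect_lt(max(abs(cv0$lli)), 1e-6)
})

test_that("a strongly tuned cell wins on every fold", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(B = tuning_place1d(220, 30, 2.2)))
  y <- generate_ln_spikes(cell, ses, seed = 15)
  cv <- crossvalidate(fx_vr_design(), y, "B")
  expect_true(all(cv$lli > 0))
})

test_that("forward selection recovers simple and conjunctive cells", {
  ses <- fx_vr_session()
  des <- fx_vr_design()
  pos <- ground_truth_cell(log(0.1), list(B = tuning_place1d(100, 30, 2)))
  y1 <- generate_ln_spikes(pos, ses, seed = 16)
  s1 <- forward_select(des, y1)
  expect_identical(s1$selected, "B")
  conj <- ground_truth_cell(log(0.1),
                            list(B = tuning_place1d(300, 35, 2),
                                 B_s = tuning_linear(0.03, 15)))
  y2 <- generate_ln_spikes(conj, ses, seed = 17)
  s2 <- forward_select(des, y2)
  expect_setequal(s2$selected, c("B", "B_s"))
  # the dominant variable enters first
  expect_identical(s2$selected[1], "B")
  # a cell with no tuning is classified as encoding nothing
  y0 <- generate_ln_spikes(ground_truth_cell(log(0.1)), ses, seed = 18)
  s0 <- forward_select(des, y0)
  expect_length(s0$selected, 0)
})

test_that("ln_fit methods expose the standard modelling surface", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(B = tuning_place1d(100, 30, 2)))
  y <- generate_ln_spikes(cell, ses, seed = 19)
  fit <- ln_fit(fx_vr_design(), y, "B")
  expect_s3_class(fit, "ln_fit")
  expect_named(coef(fit)[1], "b0")
  expect_equal(length(coef(fit)), 21)   # intercept + 20 circular bins
  expect_true(is.finite(logLik(fit)))
  r <- predict(fit, type = "rate")
  expect_true(all(r > 0))
  expect_equal(length(r), nrow(fit$design$X))
  # simulate() round-trips through the generative model
  ysim <- simulate(fit, seed = 3)
  expect_true(all(ysim >= 0))
  expect_equal(mean(ysim), mean(exp(lnspike:::fit_eta(fit))),
               tolerance = 0.05)
  expect_equal(length(residuals(fit)), length(r))
  expect_output(print(fit), "Linear-nonlinear")
  expect_output(print(summary(fit)), "mean rate")
  # prediction on new data with frozen knots
  ses2 <- simulate_vr_behavior(behavior_spec("vr_track", 120, seed = 77))
  p2 <- predict(fit, newdata = ses2, type = "rate")
  expect_true(all(is.finite(p2)))
})
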