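test_that("permutation nulls preserve marginals; shifts preserve autocorrelation", {
  set.seed(71)
  v <- rnorm(2000)
  perm <- sample(v)
  expect_identical(sort(perm), sort(v))
  y <- rpois(2000, 0.2)
  ys <- lnspike:::circshift_vec(y, 700)
  expect_identical(sort(ys), sort(y))
  # circular autocorrelation of the shifted train is unchanged
  circ_acf <- function(x, lag) cor(x, lnspike:::circshift_vec(x, lag))
  for (lag in c(1, 5, 20))
    expect_equal(circ_acf(ys, lag), circ_acf(y, lag), tolerance = 1e-12)
})

test_that("shuffle configuration enforces its invariants", {
  expect_error(shuffle_config(min_shift = 5), "20 s")
  expect_error(shuffle_config(two_sided = c(0, 97.5)))
  expect_s3_class(shuffle_config(), "shuffle_config")
})

test_that("linear velocity cells are significant; V-shaped need the symmetric rule", {
  ses <- fx_vr_session()
  cfgs <- shuffle_config(n_shuffles = 200, seed = 2)
  lin <- ground_truth_cell(log(0.08), list(dE_h = tuning_linear(0.35)))
  yl <- generate_ln_spikes(lin, ses, seed = 72)
  sl <- shuffle_significance(ses, yl, "dE_h", cfgs)
  expect_true(sl$significant)
  # constructed fixture with an exactly symmetric velocity distribution:
  # the V-shaped cell's linear correlation is zero by symmetry, so only
  # the side-correlation (symmetric) rule can detect it
  set.seed(73)
  n <- 30000
  z <- abs(lnspike:::ou_process(n / 2, 0.02, 0, 1.4, 0.3))
  v <- as.vector(rbind(z, -z))          # symmetric interleaved trace
  sym_ses <- behavior_session(seq(0, by = 0.02, length.out = n),
                              list(dE_h = v), sample_rate = 50,
                              arena = list(kind = "vr_track", length = 400,
                                           n_landmarks = 5))
  # V-shaped rate, with counts mirrored across the paired +/-v samples so
  # the overall linear correlation is exactly zero
  lam <- exp(log(0.08) + 1.2 * (z / 3)^2)
  set.seed(173)
  yz <- rpois(n / 2, lam)
  yv <- as.integer(as.vector(rbind(yz, yz)))
  expect_equal(cor(v, yv), 0, tolerance = 1e-12)
  sv <- shuffle_significance(sym_ses, yv, "dE_h", cfgs)
  expect_false(sv$significant)          # plain linear rule misses it
  expect_equal(sv$symmetric, "V")       # the symmetric rule catches it
  lam_i <- exp(log(0.3) - 1.2 * (z / 3)^2)
  yzi <- rpois(n / 2, lam_i)
  yi <- as.integer(as.vector(rbind(yzi, yzi)))
  si <- shuffle_significance(sym_ses, yi, "dE_h", cfgs)
  expect_equal(si$symmetric, "inverse-V")
})

test_that("pooled mode combines nulls across cells", {
  ses <- fx_vr_session()
  lin <- ground_truth_cell(log(0.08), list(dE_h = tuning_linear(0.35)))
  yl <- generate_ln_spikes(lin, ses, seed = 75)
  other <- matrix(rnorm(600, 0, 0.01), ncol = 3,
                  dimnames = list(NULL, c("score", "below", "above")))
  sp <- shuffle_significance(ses, yl, "dE_h",
                             shuffle_config(n_shuffles = 100, mode = "pooled",
                                            seed = 2),
                             pooled_null = other)
  expect_true(sp$significant)
})

test_that("constant firing rates are reported not significant, never errors", {
  ses <- fx_vr_session()
  s0 <- shuffle_significance(ses, integer(length(ses$time)), "dE_h",
                             shuffle_config(n_shuffles = 50, seed = 1))
  expect_false(s0$significant)
  expect_true(is.na(s0$score))
})

test_that("sessions shorter than twice the minimum shift are rejected", {
  short <- lnspike:::subset_session(fx_vr_session(), 1:1500)  # 30 s
  expect_error(shuffle_significance(short, integer(1500), "dE_h",
                                    shuffle_config()),
               "twice the minimum shift")
})

test_that("regeneration without dropped variables matches the fit rate", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1),
                            list(B = tuning_place1d(150, 35, 2),
                                 E_h = tuning_poly(c(0.9, 0), c(-3, 3))))
  y <- generate_ln_spikes(cell, ses, seed = 76)
  fit <- ln_fit(fx_vr_design(), y, c("B", "E_h"))
  keep_all <- regenerate_without_variables(fit, character(0), seed = 3)
  expect_equal(keep_all$log_rate, lnspike:::fit_eta(fit), tolerance = 1e-12)
  expect_identical(keep_all$kept, c("B", "E_h"))
  # dropping the dominant variable lowers held-out performance
  ydrop <- regenerate_without_variables(fit, "B", seed = 4)$counts
  cv_orig <- crossvalidate(fx_vr_design(), y, c("B", "E_h"))
  cv_drop <- crossvalidate(fx_vr_design(), ydrop, c("B", "E_h"))
  expect_lt(mean(cv_drop$lli), mean(cv_orig$lli))
  expect_error(regenerate_without_variables(fit, "H_p"), "subset")
  # dropping everything leaves the bias-only model
  bias_only <- regenerate_without_variables(fit, c("B", "E_h"), seed = 5)
  expect_equal(unique(bias_only$log_rate), fit$b0)
})

test_that("zero-spike cells are never selected and never error", {
  ses <- fx_vr_session()
  des <- fx_vr_design()
  sel <- forward_select(des, integer(length(ses$time)))
  expect_length(sel$selected, 0)
  fd <- estimate_false_detection(ses, list(integer(length(ses$time))), "E_h",
                                 n_reps = 2, seed = 3)
  expect_equal(fd$rate, 0)
  expect_equal(fd$failures, 0L)
})

test_that("false-detection estimation returns calibrated structure", {
  ses <- fx_vr_session()
  cell <- ground_truth_cell(log(0.1), list(B = tuning_place1d(150, 35, 2)))
  cells <- lapply(81:82, function(s) generate_ln_spikes(cell, ses, seed = s))
  fd <- estimate_false_detection(ses, cells, "E_h", n_reps = 1, seed = 5)
  expect_gte(fd$rate, 0); expect_lte(fd$rate, 1)
  expect_length(fd$detected, 2)
  expect_true(fd$ci[1] <= fd$rate && fd$rate <= fd$ci[2])
})
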