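#' Preset display bounds for tuning curves
#'
#' Head position curves are displayed over at most +/- 50 deg, azimuthal
#' head velocity over +/- 100 deg/s, horizontal eye variables over +/- 3
#' and vertical ones over +/- 2 (% eye width, or per second); azimuth
#' head direction spans the full circle. Other variables have no preset
#' and use the behavioral percentile range alone.
#'
#' @param symbol Variable symbol.
#' @return `c(lo, hi)` or `NULL`.
#' @export
preset_display_bounds <- function(symbol) {
  switch(symbol,
         H_p = c(-50, 50), H_r = c(-50, 50), dH_a = c(-100, 100),
         E_h = c(-3, 3), dE_h = c(-3, 3), E_v = c(-2, 2), dE_v = c(-2, 2),
         H_a = c(0, 360), NULL)
}

# display range: behavioral (knot) range intersected with the preset
display_range <- function(design, symbol) {
  k <- design$knots[[symbol]]
  if (is.list(k)) stop("display range is one-dimensional; got 2-D variable")
  cfg <- design$configs[[symbol]]
  rng <- if (cfg$circular) c(k[1], k[1] + cfg$period) else range(k)
  b <- preset_display_bounds(symbol)
  if (!is.null(b) && !cfg$circular) rng <- c(max(rng[1], b[1]), min(rng[2], b[2]))
  if (rng[1] >= rng[2]) stop("empty display range for ", symbol)
  rng
}

new_tuning_curve <- function(variable, centers, rate, sem = NULL,
                             fold_rates = NULL, range = NULL,
                             kind = "model", occupancy = NULL) {
  if (is.null(range)) range <- base::range(centers)
  structure(list(variable = variable, centers = centers, rate = rate,
                 sem = sem, fold_rates = fold_rates, range = range,
                 kind = kind, occupancy = occupancy),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s (%s), %d bins on [%.3g, %.3g], rate %.2f-%.2f spikes/s\n",
              x$variable, x$kind, length(x$centers), x$range[1], x$range[2],
              min(x$rate, na.rm = TRUE), max(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$centers, x$rate, type = "l", xlab = x$variable,
                 ylab = "firing rate (spikes/s)", ...)
  if (!is.null(x$sem)) {
    graphics::lines(x$centers, x$rate + x$sem, lty = 3)
    graphics::lines(x$centers, pmax(0, x$rate - x$sem), lty = 3)
  }
  invisible(x)
}

#' Model-derived tuning curve
#'
#' Expected firing rate as a function of one variable with every other
#' encoded variable's contribution averaged out:
#' `C_i(m) = exp(Y_i(m) w_i) * gamma / dt`, where `gamma` is the
#' baseline `exp(b0)` times the product over the other variables of the
#' time-average of `exp(X_v(t) w_v)`. With cross-validation results the
#' per-fold curves give the dispersion (sem over 10 model folds).
#'
#' @param fit An [ln_fit()]. @param variable A fitted 1-D variable (for
#'   2-D body position use `model_tuning_map`).
#' @param M Number of curve bins (default 200).
#' @param cv Optional [crossvalidate()] result for fold-wise sem.
#' @return A `tuning_curve` object (rates in spikes/s).
#' @export
model_tuning_curve <- function(fit, variable, M = 200, cv = NULL) {
  if (!variable %in% fit$variables) stop("variable not in fit: ", variable)
  design <- fit$design
  rng <- display_range(design, variable)
  cfg <- design$configs[[variable]]
  centers <- seq(rng[1] + diff(rng) / (2 * M), by = diff(rng) / M,
                 length.out = M)
  Y <- spline_design_1d(centers, design$knots[[variable]],
                        circular = cfg$circular, period = cfg$period,
                        s = cfg$s)
  curve_from_coefs <- function(coefs) {
    b0 <- coefs[1]
    w <- split_coefs(coefs[-1], fit$variables, design)
    gamma <- exp(b0)
    for (v in fit$variables) {
      if (v == variable) next
      Xv <- design$X[, design$cols[[v]], drop = FALSE]
      gamma <- gamma * mean(exp(as.numeric(Xv %*% w[[v]])))
    }
    as.numeric(exp(Y %*% w[[variable]])) * gamma / fit$dt
  }
  rate <- curve_from_coefs(fit$coef_vector)
  fold_rates <- sem <- NULL
  if (!is.null(cv)) {
    fold_rates <- vapply(cv$fold_fits, curve_from_coefs, numeric(M))
    sem <- apply(fold_rates, 1, stats::sd) / sqrt(ncol(fold_rates))
  }
  new_tuning_curve(variable, centers, rate, sem, fold_rates, rng, "model")
}

# split a stacked coefficient vector back into per-variable weights
split_coefs <- function(coefs, variables, design) {
  w <- list(); p0 <- 0L
  for (sym in variables) {
    k <- length(design$cols[[sym]])
    w[[sym]] <- coefs[p0 + seq_len(k)]
    p0 <- p0 + k
  }
  w
}

#' Model-derived 2-D position tuning map
#'
#' @param fit An [ln_fit()] containing the 2-D `B` variable.
#' @param M Grid resolution per axis.
#' @return List with `x`, `y` grids and `rate` matrix (spikes/s).
#' @export
model_tuning_map <- function(fit, M = 40) {
  design <- fit$design
  k <- design$knots$B
  if (!is.list(k)) stop("session has no 2-D position variable")
  gx <- seq(k$x[1], k$x[length(k$x)], length.out = M)
  gy <- seq(k$y[1], k$y[length(k$y)], length.out = M)
  grid <- expand.grid(x = gx, y = gy)
  Y <- spline_design_2d(grid$x, grid$y, k$x, k$y, s = design$configs$B$s)
  w <- split_coefs(fit$coef_vector[-1], fit$variables, design)
  gamma <- exp(fit$b0)
  for (v in setdiff(fit$variables, "B")) {
    Xv <- design$X[, design$cols[[v]], drop = FALSE]
    gamma <- gamma * mean(exp(as.numeric(Xv %*% w[[v]])))
  }
  rate <- matrix(as.numeric(exp(Y %*% w$B)) * gamma / fit$dt, M, M)
  list(x = gx, y = gy, rate = rate)
}

#' Raw (occupancy-normalized) tuning curve
#'
#' Spikes per second of occupancy in 20 bins over the restricted
#' behavioral range, smoothed by robust locally weighted linear
#' regression over 7 bins. Zero-occupancy bins are reported as NA, never
#' interpolated.
#'
#' @param session A [behavior_session()]. @param counts Spike counts per
#'   bin. @param variable A 1-D variable symbol.
#' @param n_bins Number of bins (default 20).
#' @param smooth Logical; apply the 7-bin robust lowess (default TRUE).
#' @return A `tuning_curve` object with `occupancy` (seconds per bin).
#' @export
raw_tuning_curve <- function(session, counts, variable, n_bins = 20,
                             smooth = TRUE) {
  vals <- variable_values(session, variable)
  if (is.matrix(vals)) stop("raw_tuning_curve is one-dimensional")
  open_field <- identical(session$arena$kind, "open_field")
  wnd <- if (open_field) c(2.5, 97.5) else c(1, 99)
  circ <- variable == "H_a" ||
    (variable == "B" && !open_field)
  rng <- if (circ) {
    if (variable == "H_a") c(0, 360) else c(0, session$arena$length)
  } else stats::quantile(vals[is.finite(vals)], wnd / 100, names = FALSE)
  b <- preset_display_bounds(variable)
  if (!is.null(b) && !circ) rng <- c(max(rng[1], b[1]), min(rng[2], b[2]))
  msk <- Reduce(`&`, session$mask[intersect(names(session$mask),
                                            if (variable == "B") "B" else variable)],
                rep(TRUE, length(vals)))
  use <- is.finite(vals) & msk & vals >= rng[1] & vals <= rng[2]
  if (!any(use)) stop("no occupancy inside the restricted range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(n_bins, pmax(1L, findInterval(vals[use], edges,
                                            rightmost.closed = TRUE)))
  occ <- tabulate(idx, n_bins) / session$sample_rate
  spk <- vapply(seq_len(n_bins), function(i) sum(counts[use][idx == i]),
                numeric(1))
  rate <- ifelse(occ > 0, spk / occ, NA_real_)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  sm <- rate
  if (smooth) {
    ok <- !is.na(rate)
    if (sum(ok) >= 3) {
      lw <- stats::lowess(centers[ok], rate[ok], f = min(1, 7 / sum(ok)),
                          iter = 3)
      sm[ok] <- lw$y
    }
  }
  new_tuning_curve(variable, centers, sm, range = rng, kind = "raw",
                   occupancy = occ)
}

# subset a behavior session by a logical/integer time index
subset_session <- function(session, idx) {
  behavior_session(session$time[idx],
                   lapply(session$channels, `[`, idx),
                   lapply(session$mask, `[`, idx),
                   session$sample_rate, session$arena)
}

#' Tuning-curve stability across session halves
#'
#' Refits the full selected model separately on the first and second
#' halves of the session, restricts both model-derived curves to the
#' intersection of their behavioral ranges (up-sampling the shorter by
#' linear interpolation), and returns their Pearson correlation.
#'
#' @param session,counts Full session and spike counts.
#' @param selected Character vector of the cell's selected variables.
#' @param variable The variable whose stability is quantified.
#' @param configs Variable configurations (default
#'   [default_variable_configs()]).
#' @param M Curve resolution.
#' @param beta Penalty.
#' @return Pearson correlation (NA if the half ranges do not overlap).
#' @export
tuning_stability <- function(session, counts, selected, variable,
                             configs = NULL, M = 200, beta = 1) {
  stopifnot(variable %in% selected)
  if (is.null(configs)) configs <- default_variable_configs(session)
  n <- length(session$time)
  halves <- list(seq_len(floor(n / 2)), (floor(n / 2) + 1L):n)
  curves <- lapply(halves, function(idx) {
    half <- subset_session(session, idx)
    des <- assemble_design(half, configs[selected],
                           min_bins = min(1000, floor(length(idx) / 2)))
    fit <- ln_fit(des, counts[idx], selected, beta = beta)
    model_tuning_curve(fit, variable, M = M)
  })
  lo <- max(curves[[1]]$range[1], curves[[2]]$range[1])
  hi <- min(curves[[1]]$range[2], curves[[2]]$range[2])
  if (lo >= hi) return(NA_real_)
  clip <- lapply(curves, function(tc) {
    keep <- tc$centers >= lo & tc$centers <= hi
    list(x = tc$centers[keep], y = tc$rate[keep])
  })
  n1 <- length(clip[[1]]$x); n2 <- length(clip[[2]]$x)
  if (min(n1, n2) < 3) return(NA_real_)
  if (n1 != n2) {
    short <- which.min(c(n1, n2)); long <- 3L - short
    clip[[short]] <- list(
      x = clip[[long]]$x,
      y = stats::approx(clip[[short]]$x, clip[[short]]$y,
                        xout = clip[[long]]$x, rule = 2)$y)
  }
  stats::cor(clip[[1]]$y, clip[[2]]$y)
}

#' Classify the shape of a tuning curve by polynomial degree
#'
#' Range-normalizes the curve to `[0, 1]` (head pitch/roll curves are
#' additionally Gaussian-smoothed over a 20-bin window), then fits
#' polynomials of degree 1-5 by least squares and accepts the lowest
#' degree whose fraction of error explained over the flat (mean)
#' baseline is at least `threshold`. Classification is attempted only if
#' the curve covers at least 50% (head variables) or 80% (eye variables)
#' of the preset display range.
#'
#' @param curve A `tuning_curve`.
#' @param threshold Fraction-of-error-explained bar (default 0.9).
#' @return An object of class `"shape_classification"`: `degree` (1-5 or
#'   NA for unclassified), `fraction`, `direction`
#'   (`"positive"`/`"negative"`: side of the range midpoint holding the
#'   curve maximum), `preferred` (location of the global extremum among
#'   detected peaks/valleys), `coverage_ok`, and `extremum`
#'   (`"peak"`/`"valley"`).
#' @export
classify_shape <- function(curve, threshold = 0.9) {
  sym <- curve$variable
  b <- preset_display_bounds(sym)
  need <- if (grepl("^d?E", sym)) 0.8 else 0.5
  coverage_ok <- TRUE
  if (!is.null(b)) coverage_ok <- diff(curve$range) / diff(b) >= need
  y <- curve$rate
  keep <- !is.na(y)
  y <- y[keep]; x <- curve$centers[keep]
  if (!coverage_ok || length(y) < 7)
    return(structure(list(degree = NA_integer_, fraction = NA_real_,
                          direction = NA_character_, preferred = NA_real_,
                          coverage_ok = coverage_ok, extremum = NA_character_),
                     class = "shape_classification"))
  rngy <- range(y)
  if (diff(rngy) < 1e-12) {
    return(structure(list(degree = NA_integer_, fraction = NA_real_,
                          direction = NA_character_, preferred = NA_real_,
                          coverage_ok = coverage_ok, extremum = NA_character_,
                          degenerate = TRUE),
                     class = "shape_classification"))
  }
  yn <- (y - rngy[1]) / diff(rngy)
  if (sym %in% c("H_p", "H_r")) yn <- gauss_smooth(yn, 4, window = 20)
  xs <- 2 * (x - min(x)) / diff(range(x)) - 1
  mse0 <- mean((yn - mean(yn))^2)
  degree <- NA_integer_; fraction <- NA_real_
  for (d in 1:5) {
    fitd <- stats::lm.fit(stats::poly(xs, d, raw = TRUE, simple = TRUE) |>
                            cbind(1) |> unname(), yn)
    fr <- 1 - mean(fitd$residuals^2) / mse0
    if (fr >= threshold) { degree <- d; fraction <- fr; break }
    if (d == 5L) fraction <- fr
  }
  mid <- mean(curve$range)
  direction <- if (x[which.max(yn)] > mid) "positive" else "negative"
  pv <- find_extrema(x, yn)
  structure(list(degree = degree, fraction = fraction, direction = direction,
                 preferred = pv$location, coverage_ok = coverage_ok,
                 extremum = pv$type),
            class = "shape_classification")
}

#' @export
print.shape_classification <- function(x, ...) {
  if (is.na(x$degree)) cat("unclassified tuning curve")
  else cat(sprintf("degree-%d tuning (fraction of error explained %.3f)",
                   x$degree, x$fraction))
  if (!is.na(x$preferred))
    cat(sprintf("; %s at %.3g", x$extremum %||% "extremum", x$preferred))
  cat("\n")
  invisible(x)
}

# global extremum among detected peaks and valleys (interior extrema
# preferred; falls back to the curve's global max/min at the borders)
find_extrema <- function(x, y) {
  pk <- pracma::findpeaks(y)
  vl <- pracma::findpeaks(-y)
  cand <- data.frame(val = numeric(0), at = integer(0), type = character(0))
  if (!is.null(pk))
    cand <- rbind(cand, data.frame(val = pk[, 1], at = pk[, 2], type = "peak"))
  if (!is.null(vl))
    cand <- rbind(cand, data.frame(val = -vl[, 1], at = vl[, 2], type = "valley"))
  gmax <- max(y); gmin <- min(y)
  has_peak <- nrow(cand) && any(cand$type == "peak" & cand$val >= gmax - 1e-12)
  has_valley <- nrow(cand) && any(cand$type == "valley" & cand$val <= gmin + 1e-12)
  if (has_peak) {
    i <- cand$at[cand$type == "peak"][which.max(cand$val[cand$type == "peak"])]
    return(list(location = x[i], type = "peak"))
  }
  if (has_valley) {
    i <- cand$at[cand$type == "valley"][which.min(cand$val[cand$type == "valley"])]
    return(list(location = x[i], type = "valley"))
  }
  # monotone curve: global extremum at a border
  if (abs(gmax - mean(y)) >= abs(gmin - mean(y)))
    list(location = x[which.max(y)], type = "peak")
  else list(location = x[which.min(y)], type = "valley")
}

#' Classify a velocity tuning curve into its subtype
#'
#' Fits a line to the curve on either side of zero velocity. Degree-1
#' curves are linear-asymmetric (`L_as`) with the direction of the
#' slope. Higher-degree curves are nonlinear-symmetric (`NL_s`) when the
#' side slopes have opposite signs and the smaller-magnitude slope is at
#' least half the larger (V-shaped `NL_s-pos` when the above-zero slope
#' is positive, inverse-V `NL_s-neg` otherwise), and otherwise
#' nonlinear-asymmetric (`NL_as`) preferring the larger-|slope| side.
#'
#' @param curve A velocity `tuning_curve` whose range contains zero.
#' @param shape Optional precomputed [classify_shape()] result.
#' @param symmetry_ratio Slope-ratio threshold for the symmetric class
#'   (default 0.5).
#' @return A list: `subtype` (`"L_as"`, `"NL_as"`, `"NL_s-pos"`,
#'   `"NL_s-neg"` or NA), `slope_below`, `slope_above`, `direction`
#'   (`"positive"`/`"negative"`), `preferred` and `degree`.
#' @export
classify_velocity_subtype <- function(curve, shape = NULL,
                                      symmetry_ratio = 0.5) {
  if (!(curve$range[1] < 0 && curve$range[2] > 0))
    stop("velocity subtype requires zero inside the curve range")
  if (is.null(shape)) shape <- classify_shape(curve)
  keep <- !is.na(curve$rate)
  x <- curve$centers[keep]; y <- curve$rate[keep]
  below <- x < 0; above <- x > 0
  if (sum(below) < 3 || sum(above) < 3)
    stop("too few bins on one side of zero")
  m_lo <- stats::cov(x[below], y[below]) / stats::var(x[below])
  m_hi <- stats::cov(x[above], y[above]) / stats::var(x[above])
  pv <- find_extrema(x, y)
  if (!is.na(shape$degree) && shape$degree == 1L) {
    m_all <- stats::cov(x, y) / stats::var(x)
    return(list(subtype = "L_as", slope_below = m_lo, slope_above = m_hi,
                direction = if (m_all > 0) "positive" else "negative",
                preferred = pv$location, degree = shape$degree))
  }
  if (is.na(shape$degree))
    return(list(subtype = NA_character_, slope_below = m_lo,
                slope_above = m_hi, direction = NA_character_,
                preferred = pv$location, degree = NA_integer_))
  opposite <- sign(m_lo) == -sign(m_hi) && sign(m_lo) != 0
  ratio <- min(abs(m_lo), abs(m_hi)) / max(abs(m_lo), abs(m_hi))
  if (opposite && ratio >= symmetry_ratio) {
    list(subtype = if (m_hi > 0) "NL_s-pos" else "NL_s-neg",
         slope_below = m_lo, slope_above = m_hi,
         direction = if (m_hi > 0) "positive" else "negative",
         preferred = pv$location, degree = shape$degree)
  } else {
    side <- if (abs(m_hi) >= abs(m_lo)) "positive" else "negative"
    list(subtype = "NL_as", slope_below = m_lo, slope_above = m_hi,
         direction = side, preferred = pv$location, degree = shape$degree)
  }
}

#' Unique contribution of a variable to model performance
#'
#' Difference between the cross-validated performance of the selected
#' model and of a reduced model with the variable removed (refit on the
#' same folds). The primary measure is the spike-normalized held-out
#' log-likelihood increase (bits/spike); a normalized variant
#' (`1 - LLI_reduced / LLI_selected`) and a correlation-based analogue
#' (Gaussian-smoothed spike train, 20-bin window, correlated with each
#' model's rate) are also returned.
#'
#' @param selection An [forward_select()] result whose selected set
#'   contains `variable` and at least one other variable.
#' @param variable The variable of interest.
#' @return List with `contribution` (bits/spike), `normalized`,
#'   `correlation_delta`, and the reduced model's cross-validation.
#' @export
variable_contribution <- function(selection, variable) {
  stopifnot(inherits(selection, "ln_select"))
  sel <- selection$selected
  if (!(variable %in% sel) || length(sel) < 2)
    stop("contribution requires the variable plus at least one other selected variable")
  reduced <- setdiff(sel, variable)
  cv_red <- crossvalidate(selection$design, selection$counts, reduced,
                          beta = selection$beta)
  lli_sel <- mean(selection$cv$lli_per_spike, na.rm = TRUE)
  lli_red <- mean(cv_red$lli_per_spike, na.rm = TRUE)
  y <- selection$counts
  ys <- gauss_smooth(y, 4, window = 20)
  r_sel <- stats::cor(ys, predict.ln_fit(selection$fit, type = "count"))
  r_red <- stats::cor(ys, predict.ln_fit(cv_red$fit, type = "count"))
  list(contribution = lli_sel - lli_red,
       normalized = if (abs(lli_sel) > 1e-12) 1 - lli_red / lli_sel else NA_real_,
       correlation_delta = r_sel - r_red,
       reduced_cv = cv_red)
}
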