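#' Cardinal spline blending matrix
#'
#' The 4x4 cardinal (Catmull-Rom family) blending matrix with tension `s`.
#' Row weights `[a^3 a^2 a 1] %*% M` give the contribution of a value to
#' the four control points surrounding it; every weight row sums to 1
#' (partition of unity).
#'
#' @param s Spline tension in `[0.5, 0.7]`; default 0.6.
#' @return A 4x4 numeric matrix.
#' @export
spline_blend_matrix <- function(s = 0.6) {
  rbind(
    c(-s,     2 - s, s - 2,     s),
    c(2 * s,  s - 3, 3 - 2 * s, -s),
    c(-s,     0,     s,         0),
    c(0,      1,     0,         0)
  )
}

#' Configuration of one model variable
#'
#' Describes how a behavioral variable is binned into spline control
#' points, whether it is circular, and which percentile window of its
#' behavioral distribution is admitted into the model.
#'
#' @param symbol Variable symbol, e.g. `"B"`, `"H_p"`, `"dE_h"`.
#' @param channels Session channel name(s) backing the variable
#'   (two channels, e.g. `c("B_x","B_y")`, make a 2-D variable).
#' @param n_bins Number of spline control points (per axis for 2-D).
#' @param bin_width Alternative to `n_bins`: control-point spacing in the
#'   variable's units; the count is derived from the windowed range.
#' @param circular Logical; control points wrap (azimuth head direction,
#'   virtual-track position).
#' @param period Period of a circular variable (360 for angles; the track
#'   length for virtual position).
#' @param window Percentile window `c(lo, hi)` admitted into the model,
#'   or `NULL` for circular variables (whole range used).
#' @param s Spline tension.
#' @return An object of class `"variable_config"`.
#' @export
variable_config <- function(symbol, channels = symbol, n_bins = NULL,
                            bin_width = NULL, circular = FALSE,
                            period = 360, window = c(2.5, 97.5), s = 0.6) {
  if (is.null(n_bins) && is.null(bin_width))
    stop("one of n_bins or bin_width is required")
  if (!is.null(n_bins) && any(n_bins < 4))
    stop("cubic spline support requires >= 4 control points")
  if (!is.null(window)) {
    if (length(window) != 2 || any(window <= 0) || any(window >= 100) ||
        window[1] >= window[2])
      stop("window must be percentiles (lo, hi) inside (0, 100)")
  }
  structure(list(symbol = symbol, channels = channels, n_bins = n_bins,
                 bin_width = bin_width, circular = circular, period = period,
                 window = window, s = s),
            class = "variable_config")
}

#' Default variable configurations for a session
#'
#' Open-field sessions use `round(arena_cm * 15/100)` position bins per
#' axis, 10 azimuth bins, 5 cm/s speed bins, 8 bins for pitch, roll and
#' azimuthal head velocity, and a 2.5-97.5 percentile inclusion window.
#' Virtual-track (head-fixed) sessions use 20 circular position bins,
#' 5 cm/s speed bins, 5 bins per eye variable, and a 1-99 window.
#'
#' @param session A [behavior_session()].
#' @param s Spline tension applied to all variables.
#' @return Named list of [variable_config()] objects.
#' @export
default_variable_configs <- function(session, s = 0.6) {
  stopifnot(inherits(session, "behavior_session"))
  if (identical(session$arena$kind, "open_field")) {
    nx <- max(4L, round(session$arena$width * 15 / 100))
    ny <- max(4L, round(session$arena$height * 15 / 100))
    w <- c(2.5, 97.5)
    list(
      B    = variable_config("B", c("B_x", "B_y"), n_bins = c(nx, ny), window = w, s = s),
      B_s  = variable_config("B_s", n_bins = NULL, bin_width = 5, window = w, s = s),
      H_a  = variable_config("H_a", n_bins = 10, circular = TRUE, period = 360,
                             window = NULL, s = s),
      H_p  = variable_config("H_p", n_bins = 8, window = w, s = s),
      H_r  = variable_config("H_r", n_bins = 8, window = w, s = s),
      dH_a = variable_config("dH_a", n_bins = 8, window = w, s = s)
    )
  } else {
    w <- c(1, 99)
    eye <- function(sym) variable_config(sym, n_bins = 5, window = w, s = s)
    list(
      B    = variable_config("B", n_bins = 20, circular = TRUE,
                             period = session$arena$length, window = NULL, s = s),
      B_s  = variable_config("B_s", n_bins = NULL, bin_width = 5, window = w, s = s),
      E_h  = eye("E_h"), E_v = eye("E_v"), dE_h = eye("dE_h"), dE_v = eye("dE_v")
    )
  }
}

#' Resolve spline control points for observed values
#'
#' Non-circular variables place `n_bins` evenly spaced control points
#' across the percentile-windowed range of the observed values (or a
#' count derived from `bin_width`). Circular variables place `n_bins`
#' points over one period.
#'
#' @param config A [variable_config()].
#' @param values Observed values of the variable (one axis).
#' @param axis Axis index for 2-D variables (selects the per-axis bin
#'   count).
#' @return Numeric vector of control-point locations (knots).
#' @export
resolve_knots <- function(config, values, axis = 1L) {
  if (config$circular) {
    W <- config$n_bins[1]
    return(seq(0, config$period, length.out = W + 1L)[seq_len(W)])
  }
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to place knots on")
  if (is.null(config$window)) rng <- range(v)
  else rng <- stats::quantile(v, config$window / 100, names = FALSE, type = 7)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)  # degenerate (constant) trace
  W <- config$n_bins[min(axis, length(config$n_bins))]
  if (is.null(W)) W <- max(4L, ceiling(diff(rng) / config$bin_width) + 1L)
  seq(rng[1], rng[2], length.out = W)
}

#' Cardinal-spline state vector for one value
#'
#' Computes the fractional distance `alpha` of `value` between its two
#' nearest control points and returns the four blending weights placed at
#' control points `j-1 .. j+2`. Circular variables wrap indices modulo the
#' number of control points. For non-circular variables the two phantom
#' points beyond the grid are eliminated by linear extension
#' (`w[0] = 2 w[1] - w[2]`), so returned indices always lie in `1..W`;
#' the weight sum (exactly 1) is preserved by the folding.
#'
#' @param value A single value (inside the knot range for non-circular
#'   variables).
#' @param knots Control points from [resolve_knots()].
#' @param circular Logical.
#' @param period Period for circular variables.
#' @param s Spline tension.
#' @return List with `idx` (control-point indices) and `w` (weights),
#'   or `NULL` if the value falls outside the knot range (masked sample).
#' @export
build_spline_state_vector <- function(value, knots, circular = FALSE,
                                      period = 360, s = 0.6) {
  W <- length(knots)
  if (!is.finite(value)) return(NULL)
  if (circular) {
    dz <- period / W
    y <- (value - knots[1]) %% period
    j <- floor(y / dz) + 1L
    if (j > W) j <- W  # y == period boundary guard
    a <- (y - (j - 1L) * dz) / dz
  } else {
    if (value < knots[1] || value > knots[W]) return(NULL)
    dz <- knots[2] - knots[1]
    j <- min(W - 1L, floor((value - knots[1]) / dz) + 1L)
    a <- (value - knots[j]) / dz
  }
  wts <- as.numeric(c(a^3, a^2, a, 1) %*% spline_blend_matrix(s))
  idx <- (j - 1L):(j + 2L)
  if (circular) {
    idx <- ((idx - 1L) %% W) + 1L
  } else {
    # fold phantom control points 0 and W+1 back by linear extension
    out <- numeric(W)
    for (k in 1:4) {
      i <- idx[k]; wk <- wts[k]
      if (i == 0L) {
        out[1L] <- out[1L] + 2 * wk; out[2L] <- out[2L] - wk
      } else if (i == W + 1L) {
        out[W] <- out[W] + 2 * wk; out[W - 1L] <- out[W - 1L] - wk
      } else out[i] <- out[i] + wk
    }
    keep <- which(out != 0)
    return(list(idx = keep, w = out[keep]))
  }
  # circular duplicates can collide when W == 4
  if (anyDuplicated(idx)) {
    agg <- tapply(wts, idx, sum)
    return(list(idx = as.integer(names(agg)), w = as.numeric(agg)))
  }
  list(idx = idx, w = wts)
}

# Vectorized spline design for one axis: T x W sparse matrix.
# Rows for values outside the knot range (or NA) are all-zero.
spline_design_1d <- function(values, knots, circular = FALSE, period = 360,
                             s = 0.6) {
  W <- length(knots)
  Tn <- length(values)
  M <- spline_blend_matrix(s)
  if (circular) {
    dz <- period / W
    y <- (values - knots[1]) %% period
    j <- pmin(W, floor(y / dz) + 1L)
    a <- (y - (j - 1L) * dz) / dz
    ok <- is.finite(values)
  } else {
    dz <- knots[2] - knots[1]
    ok <- is.finite(values) & values >= knots[1] & values <= knots[W]
    j <- pmin(W - 1L, pmax(1L, floor((values - knots[1]) / dz) + 1L))
    j[!is.finite(j)] <- 1L
    a <- (values - knots[j]) / dz
  }
  a[!ok] <- 0; j[!ok] <- 1L
  j <- as.integer(j)
  Wt <- cbind(a^3, a^2, a, 1) %*% M          # T x 4 weights
  rows <- rep(seq_len(Tn), 4L)
  cols <- as.vector(vapply(-1L:2L, function(o) j + o, integer(Tn)))
  wts <- as.vector(Wt)
  keep <- rep(ok, 4L)
  if (circular) {
    cols <- ((cols - 1L) %% W) + 1L
  } else {
    # phantom folding: index 0 -> +2 at 1, -1 at 2; index W+1 symmetric
    lo <- cols == 0L; hi <- cols == W + 1L
    rows <- c(rows, rows[lo], rows[hi])
    cols2 <- cols
    cols2[lo] <- 1L; cols2[hi] <- W
    cols <- c(cols2, rep(2L, sum(lo)), rep(W - 1L, sum(hi)))
    wts <- c(ifelse(lo | hi, 2 * wts, wts), -wts[lo], -wts[hi])
    keep <- c(keep, keep[lo], keep[hi])
  }
  Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = wts[keep],
                       dims = c(Tn, W))
}

# 2-D (tensor-product) spline design, e.g. open-field body position.
# Column order: x index varies fastest.
spline_design_2d <- function(x, y, knots_x, knots_y, s = 0.6) {
  Ax <- spline_design_1d(x, knots_x, s = s)
  Ay <- spline_design_1d(y, knots_y, s = s)
  Wx <- ncol(Ax); Wy <- ncol(Ay); Tn <- nrow(Ax)
  # row-wise Kronecker product (face-splitting); stays sparse
  out <- vector("list", Wy)
  for (k in seq_len(Wy)) out[[k]] <- Ax * Ay[, k]
  Matrix::drop0(do.call(cbind, out))
}
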