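#' Algebraic least-squares circle fit
#'
#' Kasa fit: solves the linear system for center and radius minimizing
#' the algebraic distance of the pixels to a circle.
#' @param x,y Pixel coordinates.
#' @return List with `cx`, `cy`, `r`.
#' @keywords internal
circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  cf <- stats::lm.fit(A, b)$coefficients
  r2 <- cf[3] + cf[1]^2 + cf[2]^2
  list(cx = unname(cf[1]), cy = unname(cf[2]),
       r = sqrt(max(r2, 0)))
}

# largest connected component of a logical mask inside a search region;
# region = c(x0, x1, y0, y1) in pixel coordinates (cols = x, rows = y)
largest_component <- function(mask, region = NULL) {
  if (!is.null(region)) {
    inside <- matrix(FALSE, nrow(mask), ncol(mask))
    ys <- max(1, region[3]):min(nrow(mask), region[4])
    xs <- max(1, region[1]):min(ncol(mask), region[2])
    inside[ys, xs] <- TRUE
    mask <- mask & inside
  }
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  best <- which.max(tab)
  idx <- which(lab == best, arr.ind = TRUE)
  list(x = idx[, 2], y = idx[, 1], n = tab[best])
}

#' Detect the pupil in one eye-camera frame
#'
#' Thresholds the frame, takes the largest connected region of pixels
#' darker than the threshold inside the search region, and fits a circle
#' to its pixels. The frame is valid only if the connected pixel count is
#' strictly between 50 and 1000.
#'
#' @param frame Numeric matrix (rows = y, cols = x) of 8-bit intensities.
#' @param intensity_threshold Pixels strictly darker than this belong to
#'   the pupil candidate.
#' @param search_region Optional `c(x0, x1, y0, y1)` region.
#' @return A list of class `"pupil_frame_result"`: `cx`, `cy`, `r`,
#'   `n_pixels`, `valid`.
#' @export
detect_pupil <- function(frame, intensity_threshold, search_region = NULL) {
  comp <- largest_component(frame < intensity_threshold, search_region)
  if (is.null(comp) || comp$n <= 50 || comp$n >= 1000)
    return(structure(list(cx = NA_real_, cy = NA_real_, r = NA_real_,
                          n_pixels = if (is.null(comp)) 0L else comp$n,
                          valid = FALSE),
                     class = "pupil_frame_result"))
  fit <- circle_fit(comp$x, comp$y)
  structure(list(cx = fit$cx, cy = fit$cy, r = fit$r, n_pixels = comp$n,
                 valid = TRUE),
            class = "pupil_frame_result")
}

#' Detect the corneal reflection in one frame
#'
#' Bright-pixel mirror of [detect_pupil()]: the largest connected region
#' of pixels brighter than the threshold inside the boundary region, with
#' a circle fit. No pixel-count window is applied beyond non-emptiness.
#'
#' @inheritParams detect_pupil
#' @param boundary_region Optional `c(x0, x1, y0, y1)` region.
#' @return A list with `cx`, `cy`, `r`, `n_pixels`, `valid`.
#' @export
detect_cr <- function(frame, intensity_threshold, boundary_region = NULL) {
  comp <- largest_component(frame > intensity_threshold, boundary_region)
  if (is.null(comp))
    return(list(cx = NA_real_, cy = NA_real_, r = NA_real_,
                n_pixels = 0L, valid = FALSE))
  fit <- circle_fit(comp$x, comp$y)
  list(cx = fit$cx, cy = fit$cy, r = fit$r, n_pixels = comp$n, valid = TRUE)
}

#' Eye axes for projecting pupil position
#'
#' The horizontal axis runs from the tear duct to the outer canthus; the
#' vertical axis is orthogonal. Eye width is the length of the horizontal
#' axis, the normalization unit for eye position.
#'
#' @param duct_xy,canthus_xy Endpoints (px) of the horizontal axis.
#' @return An object of class `"eye_axes"`.
#' @export
eye_axes <- function(duct_xy, canthus_xy) {
  h <- c(canthus_xy[1] - duct_xy[1], canthus_xy[2] - duct_xy[2])
  width <- sqrt(sum(h^2))
  if (width <= 0) stop("eye width must be positive")
  h <- h / width
  structure(list(h = h, v = c(-h[2], h[1]), width = width,
                 duct = duct_xy, canthus = canthus_xy),
            class = "eye_axes")
}

#' Build normalized eye position time series from per-frame detections
#'
#' Applies, in order: linear interpolation across invalid frames;
#' subtraction of the corneal-reflection deviation from its session mean
#' (camera-jitter reference); high-pass drift removal by subtracting a
#' 1000-point Gaussian-smoothed trace; masking of the top and bottom 1%
#' of values per coordinate; projection onto the eye axes; and division
#' by the eye width, scaled to % of eye width.
#'
#' @param pupil_xy T x 2 matrix of pupil centers (px; NA for invalid).
#' @param cr_xy T x 2 matrix of CR centers (px; NA for invalid).
#' @param axes An [eye_axes()].
#' @param max_invalid Maximum tolerated fraction of invalid pupil frames
#'   before the session is rejected (default 0.25).
#' @param drift_window Length of the Gaussian drift filter in frames
#'   (default 1000; sigma = window / 6).
#' @return List with `E_h`, `E_v` (% eye width; masked samples NA) and
#'   the logical `valid` mask.
#' @export
build_eye_timeseries <- function(pupil_xy, cr_xy, axes,
                                 max_invalid = 0.25, drift_window = 1000) {
  pupil_xy <- as.matrix(pupil_xy); cr_xy <- as.matrix(cr_xy)
  n <- nrow(pupil_xy)
  if (n < drift_window) stop("need >= ", drift_window, " frames for drift removal")
  bad <- !stats::complete.cases(pupil_xy)
  if (mean(bad) > max_invalid)
    stop("session rejected: > ", round(100 * max_invalid),
         "% of frames have invalid pupil detections")
  interp <- function(v) {
    if (all(is.na(v))) stop("no valid samples to interpolate")
    stats::approx(seq_len(n)[!is.na(v)], v[!is.na(v)], xout = seq_len(n),
                  rule = 2)$y
  }
  px <- interp(pupil_xy[, 1]); py <- interp(pupil_xy[, 2])
  crx <- interp(cr_xy[, 1]);  cry <- interp(cr_xy[, 2])
  # reference pupil position to the CR deviation from its mean
  px <- px - (crx - mean(crx))
  py <- py - (cry - mean(cry))
  sig <- drift_window / 6
  hx <- px - gauss_smooth(px, sig, window = drift_window)
  hy <- py - gauss_smooth(py, sig, window = drift_window)
  mask_ext <- function(v) {
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
    v >= q[1] & v <= q[2]
  }
  valid <- mask_ext(hx) & mask_ext(hy)
  eh <- (hx * axes$h[1] + hy * axes$h[2]) / axes$width * 100
  ev <- (hx * axes$v[1] + hy * axes$v[2]) / axes$width * 100
  eh[!valid] <- NA_real_; ev[!valid] <- NA_real_
  list(E_h = eh, E_v = ev, valid = valid)
}

#' Smooth an eye-position series and differentiate it
#'
#' Position is Gaussian-smoothed with sigma ~ 10 ms; velocity is the
#' finite difference of the smoothed position, Gaussian-smoothed with
#' sigma ~ 140 ms. Units follow the input (% eye width and % eye
#' width/s).
#'
#' @param e Eye-position series (uniformly sampled; NAs tolerated).
#' @param sample_rate Sampling rate (Hz).
#' @param pos_sigma,vel_sigma Smoothing sigmas in seconds.
#' @return List with `position` and `velocity` series.
#' @export
smooth_and_differentiate <- function(e, sample_rate = 50,
                                     pos_sigma = 0.010, vel_sigma = 0.140) {
  pos <- gauss_smooth(e, pos_sigma * sample_rate)
  vel <- deriv_series(pos, 1 / sample_rate)
  vel <- gauss_smooth(vel, vel_sigma * sample_rate)
  list(position = pos, velocity = vel)
}
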