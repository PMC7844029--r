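#' Simulate grayscale eye-camera frames
#'
#' Each frame contains a dark pupil disk at the commanded location and a
#' small bright corneal-reflection disk over a mid-gray background.
#' Optional camera jitter translates pupil and CR together, mimicking the
#' rigid frame motion the CR reference is designed to cancel.
#'
#' @param eye_trace T x 2 matrix of commanded pupil centers (px,
#'   x then y).
#' @param geometry List: `width`, `height` (frame size, px),
#'   `pupil_radius` (px; pixel count must land strictly inside the
#'   50-1000 detectability window), `pupil_intensity`, `cr_center`
#'   (c(x, y)), `cr_radius`, `cr_intensity`, `background`.
#' @param jitter_sd SD (px) of per-frame rigid camera translation.
#' @param seed Optional seed for the jitter.
#' @return List with `frames` (list of matrices, rows = y), `truth`
#'   (commanded centers), `jitter` (applied translations) and `geometry`.
#' @export
simulate_eye_frames <- function(eye_trace,
                                geometry = list(),
                                jitter_sd = 0, seed = NULL) {
  g <- utils::modifyList(list(width = 80, height = 60, pupil_radius = 10,
                              pupil_intensity = 30, cr_center = c(20, 15),
                              cr_radius = 3, cr_intensity = 240,
                              background = 128), geometry)
  area <- pi * g$pupil_radius^2
  if (area <= 50 || area >= 1000)
    stop("pupil radius outside the detectable pixel-count window (50-1000 px)")
  eye_trace <- as.matrix(eye_trace)
  if (any(eye_trace[, 1] < 1 | eye_trace[, 1] > g$width |
          eye_trace[, 2] < 1 | eye_trace[, 2] > g$height))
    stop("eye trace outside frame bounds")
  with_seed(seed, {
    n <- nrow(eye_trace)
    jit <- if (jitter_sd > 0)
      matrix(stats::rnorm(2 * n, 0, jitter_sd), ncol = 2) else
      matrix(0, n, 2)
    xs <- matrix(rep(seq_len(g$width), each = g$height), g$height)
    ys <- matrix(rep(seq_len(g$height), g$width), g$height)
    frames <- vector("list", n)
    for (t in seq_len(n)) {
      f <- matrix(g$background, g$height, g$width)
      cx <- eye_trace[t, 1] + jit[t, 1]; cy <- eye_trace[t, 2] + jit[t, 2]
      f[(xs - cx)^2 + (ys - cy)^2 <= g$pupil_radius^2] <- g$pupil_intensity
      rx <- g$cr_center[1] + jit[t, 1]; ry <- g$cr_center[2] + jit[t, 2]
      f[(xs - rx)^2 + (ys - ry)^2 <= g$cr_radius^2] <- g$cr_intensity
      frames[[t]] <- f
    }
    list(frames = frames, truth = eye_trace, jitter = jit, geometry = g)
  })
}

#' Write and read frame stacks as 8-bit grayscale PNG
#'
#' @param frames List of intensity matrices (0-255).
#' @param dir Output directory; files are `frame_000001.png`, ...
#' @return `write_frames_png` returns the file paths invisibly;
#'   `read_frames_png` returns a list of matrices.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]] / 255, paths[i])
  invisible(paths)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE))
  lapply(paths, function(p) png::readPNG(p) * 255)
}

#' Run the pupil tracker over a stack of frames
#'
#' Convenience wrapper applying [detect_pupil()] and [detect_cr()] to
#' every frame with fixed thresholds and regions.
#'
#' @param frames List of intensity matrices.
#' @param pupil_threshold,cr_threshold Intensity thresholds.
#' @param search_region,boundary_region Optional regions
#'   `c(x0, x1, y0, y1)`.
#' @return List with `pupil_xy`, `cr_xy` (T x 2, NA where invalid) and
#'   `valid`.
#' @export
track_frames <- function(frames, pupil_threshold = 80, cr_threshold = 200,
                         search_region = NULL, boundary_region = NULL) {
  n <- length(frames)
  pupil <- matrix(NA_real_, n, 2); cr <- matrix(NA_real_, n, 2)
  valid <- logical(n)
  for (t in seq_len(n)) {
    dp <- detect_pupil(frames[[t]], pupil_threshold, search_region)
    dc <- detect_cr(frames[[t]], cr_threshold, boundary_region)
    if (dp$valid) pupil[t, ] <- c(dp$cx, dp$cy)
    if (dc$valid) cr[t, ] <- c(dc$cx, dc$cy)
    valid[t] <- dp$valid
  }
  list(pupil_xy = pupil, cr_xy = cr, valid = valid)
}
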