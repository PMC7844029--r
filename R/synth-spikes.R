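#' Parametric tuning functions for ground-truth cells
#'
#' Constructors for the log-rate contributions of a simulated cell:
#' a 2-D Gaussian place field, a von Mises head-direction field, a
#' polynomial (pitch/roll/eye position), a linear ramp and a rectified
#' ramp (velocities), and a 1-D wrapped Gaussian field for virtual-track
#' position. All evaluate to finite log-rate contributions on the
#' variable's range; a non-encoded variable simply has no entry.
#'
#' @param cx,cy,center Field center.
#' @param sigma Field width.
#' @param amp Peak log-rate contribution.
#' @param mu Preferred direction (degrees).
#' @param kappa Concentration (log-rate amplitude of the cosine).
#' @param coefs Polynomial coefficients (highest degree first, as
#'   [pracma::polyval()] expects) applied to the variable scaled to
#'   `[-1, 1]` over `range`.
#' @param range Variable range used for polynomial scaling.
#' @param slope Slope in log-rate per unit.
#' @param direction `+1` or `-1`: side of `center` that drives a
#'   rectified ramp.
#' @param period Track length for wrapped fields.
#' @return A tuning descriptor (list with class `"gt_tuning"`).
#' @name gt_tuning
NULL

#' @rdname gt_tuning
#' @export
tuning_place2d <- function(cx, cy, sigma, amp = 1.5)
  structure(list(type = "place2d", cx = cx, cy = cy, sigma = sigma, amp = amp),
            class = "gt_tuning")

#' @rdname gt_tuning
#' @export
tuning_place1d <- function(center, sigma, amp = 1.5, period = 400)
  structure(list(type = "place1d", center = center, sigma = sigma, amp = amp,
                 period = period), class = "gt_tuning")

#' @rdname gt_tuning
#' @export
tuning_vonmises <- function(mu, kappa = 1)
  structure(list(type = "vonmises", mu = mu, kappa = kappa),
            class = "gt_tuning")

#' @rdname gt_tuning
#' @export
tuning_poly <- function(coefs, range)
  structure(list(type = "poly", coefs = coefs, range = range),
            class = "gt_tuning")

#' @rdname gt_tuning
#' @export
tuning_linear <- function(slope, center = 0)
  structure(list(type = "linear", slope = slope, center = center),
            class = "gt_tuning")

#' @rdname gt_tuning
#' @export
tuning_rectified <- function(slope, center = 0, direction = 1)
  structure(list(type = "rectified", slope = slope, center = center,
                 direction = direction), class = "gt_tuning")

#' Evaluate a ground-truth tuning function
#'
#' @param tun A [gt_tuning] descriptor.
#' @param values Variable values: a numeric vector, or a 2-column matrix
#'   for 2-D place fields.
#' @return Log-rate contribution per sample.
#' @export
evaluate_tuning <- function(tun, values) {
  switch(tun$type,
    place2d = {
      v <- as.matrix(values)
      tun$amp * exp(-((v[, 1] - tun$cx)^2 + (v[, 2] - tun$cy)^2) /
                      (2 * tun$sigma^2))
    },
    place1d = {
      d <- abs(values - tun$center)
      d <- pmin(d, tun$period - d)
      tun$amp * exp(-d^2 / (2 * tun$sigma^2))
    },
    vonmises = tun$kappa * cos((values - tun$mu) * pi / 180),
    poly = {
      # constant continuation outside the stated range keeps log-rates
      # bounded for rare extreme excursions
      u <- 2 * (values - tun$range[1]) / diff(tun$range) - 1
      pracma::polyval(tun$coefs, pmin(1, pmax(-1, u)))
    },
    linear = tun$slope * (values - tun$center),
    rectified = tun$slope * pmax(0, tun$direction * (values - tun$center)),
    stop("unknown tuning type: ", tun$type)
  )
}

#' Ground-truth LN model cell
#'
#' @param bias Baseline log expected count per 20 ms bin (so a bias of
#'   `log(0.1)` gives 0.1 expected spikes/bin, i.e. 5 spikes/s).
#' @param tuning Named list of [gt_tuning] descriptors keyed by variable
#'   symbol (`B`, `B_s`, `H_a`, `H_p`, `H_r`, `dH_a`, `E_h`, ...); names
#'   define the encoded-variable set.
#' @return An object of class `"ground_truth_cell"`.
#' @export
ground_truth_cell <- function(bias, tuning = list()) {
  stopifnot(all(vapply(tuning, inherits, logical(1), "gt_tuning")))
  structure(list(bias = bias, tuning = tuning,
                 encoded = names(tuning)),
            class = "ground_truth_cell")
}

# values of a model variable from the session (2-col matrix for open-field B)
variable_values <- function(session, symbol) {
  ch <- session$channels
  if (symbol == "B" && identical(session$arena$kind, "open_field"))
    return(cbind(ch$B_x, ch$B_y))
  if (!symbol %in% names(ch)) stop("channel absent from session: ", symbol)
  ch[[symbol]]
}

#' Log expected count per bin of a ground-truth cell over a session
#' @inheritParams generate_ln_spikes
#' @return Numeric vector of log expected counts per 20 ms bin.
#' @export
ground_truth_log_rate <- function(cell, session) {
  loglam <- rep(cell$bias, length(session$time))
  for (sym in cell$encoded)
    loglam <- loglam + evaluate_tuning(cell$tuning[[sym]],
                                       variable_values(session, sym))
  loglam
}

#' Draw a Poisson spike-count series from a ground-truth LN cell
#'
#' Counts per 20 ms bin are Poisson with log mean equal to the cell's
#' bias plus the sum of its tuning contributions evaluated on the
#' session, i.e. the generative form of the LN encoding model.
#'
#' @param cell A [ground_truth_cell()].
#' @param session A [behavior_session()] containing every encoded
#'   variable.
#' @param seed Integer seed; identical seeds give identical spike trains.
#' @return Integer vector of spike counts per bin.
#' @export
generate_ln_spikes <- function(cell, session, seed = NULL) {
  loglam <- ground_truth_log_rate(cell, session)
  if (any(loglam > 20)) stop("rate overflow: log-rate > 20")
  with_seed(seed, as.integer(stats::rpois(length(loglam), exp(loglam))))
}
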