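#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never leak global state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Wrap angles into [0, 360)
#' @param x Angles in degrees.
#' @return Angles wrapped to `[0, 360)`.
#' @keywords internal
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

#' Shortest signed angular difference
#'
#' Signed arc from `from` to `to`, in `(-180, 180]` degrees.
#' @param to,from Angles in degrees.
#' @keywords internal
ang_diff <- function(to, from) {
  d <- (to - from) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Gaussian smoothing of a uniformly sampled series
#'
#' Convolution with a normalized Gaussian kernel. Edges are handled by
#' renormalizing the truncated kernel, so a constant input maps to itself.
#'
#' @param x Numeric vector (NAs propagate through the kernel support).
#' @param sigma_samples Kernel standard deviation in samples.
#' @param window Kernel length in samples; default covers +/- 4 sigma.
#' @return Smoothed vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sigma_samples, window = NULL) {
  if (sigma_samples <= 0) return(x)
  if (is.null(window)) window <- 2L * ceiling(4 * sigma_samples) + 1L
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  h <- (window - 1L) %/% 2L
  k <- stats::dnorm(seq(-h, h), sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  if (n == 0) return(x)
  # pad with NA and renormalize over available samples
  xp <- c(rep(NA_real_, h), x, rep(NA_real_, h))
  ok <- !is.na(xp)
  xz <- ifelse(ok, xp, 0)
  num <- stats::filter(xz, k, sides = 2)
  den <- stats::filter(as.numeric(ok), k, sides = 2)
  out <- as.numeric(num / den)[(h + 1L):(h + n)]
  out
}

#' Discretized Ornstein-Uhlenbeck (mean-reverting) process
#'
#' Exact AR(1) discretization: the stationary marginal is
#' N(`mean`, `sd`^2) for every time constant `tau`.
#'
#' @param n Number of samples.
#' @param dt Sample interval (s).
#' @param mean Stationary mean.
#' @param sd Stationary standard deviation.
#' @param tau Autocorrelation time constant (s).
#' @param x0 Optional starting value; default draws from the stationary law.
#' @return Numeric vector of length `n`.
#' @keywords internal
ou_process <- function(n, dt, mean = 0, sd = 1, tau = 1, x0 = NULL) {
  if (sd <= 0) return(rep(mean, n))
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- if (is.null(x0)) stats::rnorm(1, mean, sd) else x0
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1L)) x[t + 1L] <- mean + phi * (x[t] - mean) + eps[t]
  x
}

#' MD5 digest of an arbitrary R object
#'
#' Serializes the object to a temporary file and hashes it with
#' [tools::md5sum()]; used to stamp result bundles with their config.
#' @param x Any serializable R object.
#' @return A character MD5 digest.
#' @keywords internal
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
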