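#' Shuffle configuration for significance controls
#'
#' @param n_shuffles Number of shuffles (default 500).
#' @param min_shift Minimum circular time shift in seconds (default 20).
#' @param two_sided Percentile thresholds for the plain rule
#'   (default 2.5/97.5).
#' @param one_sided Percentiles for the symmetric-velocity rule
#'   (default 5/95).
#' @param mode `"within_cell"` or `"pooled"`.
#' @param seed Integer seed.
#' @return An object of class `"shuffle_config"`.
#' @export
shuffle_config <- function(n_shuffles = 500, min_shift = 20,
                           two_sided = c(2.5, 97.5), one_sided = c(5, 95),
                           mode = c("within_cell", "pooled"), seed = 1) {
  mode <- match.arg(mode)
  if (min_shift < 20) stop("minimum temporal shift is 20 s")
  stopifnot(all(two_sided > 0 & two_sided < 100),
            all(one_sided > 0 & one_sided < 100))
  structure(list(n_shuffles = n_shuffles, min_shift = min_shift,
                 two_sided = two_sided, one_sided = one_sided,
                 mode = mode, seed = seed),
            class = "shuffle_config")
}

#' Empirical false-detection rate of the forward-selection procedure
#'
#' For each repetition the target variable's behavioral values are
#' randomly permuted over time (destroying any real relationship while
#' preserving the marginal exactly), the full forward-selection
#' procedure is re-run, and the fraction of runs selecting the shuffled
#' variable is returned with a binomial confidence interval.
#'
#' @param session A [behavior_session()].
#' @param cells List of spike-count vectors (one per cell).
#' @param variable Variable symbol to shuffle and score.
#' @param configs Candidate configurations.
#' @param n_reps Shuffle repetitions per cell (default 1).
#' @param seed Integer seed.
#' @param alpha Selection significance level.
#' @return List with `rate`, binomial `ci` (95%), per-run `detected`,
#'   and the count of propagated fit failures.
#' @export
estimate_false_detection <- function(session, cells, variable,
                                     configs = NULL, n_reps = 1, seed = 1,
                                     alpha = 0.05) {
  if (is.null(configs)) configs <- default_variable_configs(session)
  if (!variable %in% names(configs)) stop("unknown variable: ", variable)
  chans <- configs[[variable]]$channels
  runs <- expand.grid(cell = seq_along(cells), rep = seq_len(n_reps))
  detected <- logical(nrow(runs)); failures <- 0L
  for (i in seq_len(nrow(runs))) {
    shuffled <- with_seed(seed + 7919L * i, {
      perm <- sample(length(session$time))
      s2 <- session
      for (ch in chans) s2$channels[[ch]] <- s2$channels[[ch]][perm]
      s2
    })
    sel <- tryCatch(
      forward_select(shuffled, cells[[runs$cell[i]]], configs, alpha = alpha),
      error = function(e) NULL)
    if (is.null(sel)) { failures <- failures + 1L; next }
    detected[i] <- variable %in% sel$selected
  }
  k <- sum(detected); n <- nrow(runs) - failures
  ci <- if (n > 0) as.numeric(stats::binom.test(k, n)$conf.int) else c(NA, NA)
  list(rate = if (n > 0) k / n else NA_real_, ci = ci,
       detected = detected, failures = failures, n = n)
}

#' Regenerate a spike train with selected variables ablated
#'
#' Rebuilds the fitted rate with the design blocks and weights of the
#' dropped variables deleted, and draws a fresh Poisson spike train.
#' Running selection on the regenerated train should not re-select the
#' dropped variables above the false-detection rate.
#'
#' @param fit An [ln_fit()] of the selected model.
#' @param drop Character vector of variables to remove (subset of the
#'   fitted variables; dropping all leaves the bias-only model).
#' @param seed Integer seed for the Poisson draw.
#' @return List with `counts` (regenerated spikes over the design's
#'   retained bins), `log_rate`, and `kept` variables.
#' @export
regenerate_without_variables <- function(fit, drop = character(0), seed = 1) {
  stopifnot(inherits(fit, "ln_fit"))
  if (!all(drop %in% fit$variables))
    stop("drop must be a subset of the fitted variables")
  kept <- setdiff(fit$variables, drop)
  eta <- rep(fit$b0, length(fit$counts))
  for (v in kept) {
    Xv <- fit$design$X[, fit$design$cols[[v]], drop = FALSE]
    eta <- eta + as.numeric(Xv %*% fit$w[[v]])
  }
  counts <- with_seed(seed, as.integer(stats::rpois(length(eta),
                                                    exp(pmin(eta, 30)))))
  list(counts = counts, log_rate = eta, kept = kept)
}

# circular shift of a vector by k samples
circshift_vec <- function(x, k) {
  n <- length(x)
  k <- ((k - 1L) %% n) + 1L
  if (k == n) return(x)
  c(x[(k + 1L):n], x[1:k])
}

# Null modulation scores for a set of circular shifts, all at once.
# For each mask M over time (all / v<0 / v>0) and shift k, the Pearson
# correlation between v on M and the shifted rate needs the sums
# sum_M r_k, sum_M r_k^2 and sum_M v r_k; each is a circular
# cross-correlation with the fixed mask series, so one FFT per series
# yields every shift simultaneously.
shifted_scores <- function(vals, rate, shifts) {
  n <- length(rate)
  ok <- is.finite(vals)
  Fr <- stats::fft(rate)
  Fr2 <- stats::fft(rate^2)
  # c(k) = sum_t m(t) * x((t + k - 1) %% n + 1)
  xcorr <- function(m, Fx)
    Re(stats::fft(Conj(stats::fft(m)) * Fx, inverse = TRUE)) / n
  masks <- list(score = ok, below = ok & vals < 0, above = ok & vals > 0)
  out <- matrix(NA_real_, length(shifts), 3,
                dimnames = list(NULL, names(masks)))
  idx <- (shifts %% n) + 1L
  for (j in seq_along(masks)) {
    m <- as.numeric(masks[[j]])
    nm <- sum(m)
    if (nm < 3) next
    v <- ifelse(masks[[j]], vals, 0)
    sv <- sum(v); svv <- sum(v^2)
    den_v <- nm * svv - sv^2
    if (den_v <= 0) next
    sr <- xcorr(m, Fr)[idx]
    srr <- xcorr(m, Fr2)[idx]
    svr <- xcorr(v, Fr)[idx]
    den_r <- nm * srr - sr^2
    num <- nm * svr - sv * sr
    good <- den_r > 0
    out[good, j] <- num[good] / sqrt(den_v * den_r[good])
  }
  out
}

# modulation scores of one cell: overall correlation and the side
# correlations below/above zero used by the symmetric-velocity rule
modulation_scores <- function(vals, rate) {
  ok <- is.finite(vals) & is.finite(rate)
  v <- vals[ok]; r <- rate[ok]
  score <- if (stats::sd(r) > 0 && stats::sd(v) > 0) stats::cor(v, r) else NA_real_
  below <- v < 0; above <- v > 0
  c(score = score,
    below = if (sum(below) > 2 && stats::sd(r[below]) > 0)
      stats::cor(v[below], r[below]) else NA_real_,
    above = if (sum(above) > 2 && stats::sd(r[above]) > 0)
      stats::cor(v[above], r[above]) else NA_real_)
}

#' Shuffle-based significance of behavioral modulation
#'
#' The modulation score is the Pearson correlation between the
#' instantaneous variable and the firing rate. A null distribution is
#' built from `n_shuffles` circular time-shifts of the spike train
#' (shift > `min_shift` s, preserving the train's autocorrelation), and
#' the cell is significant when its score falls outside the two-sided
#' percentile band of the within-cell (or pooled) null. The
#' symmetric-velocity variant scores the correlations below and above
#' zero separately and flags V-shaped (below < 5th and above > 95th
#' percentile) or inverse-V (reverse) patterns.
#'
#' @param session A [behavior_session()]. @param counts Spike counts,
#'   full session length. @param variable Variable symbol.
#' @param config A [shuffle_config()].
#' @param pooled_null Optional matrix of shuffle scores from other cells
#'   (columns score/below/above) for pooled mode.
#' @return List with `score`, `side_scores`, null percentile bounds,
#'   `significant` (plain linear rule), `symmetric`
#'   (`"V"`, `"inverse-V"` or NA), and the shuffle `null` matrix.
#' @export
shuffle_significance <- function(session, counts, variable,
                                 config = shuffle_config(),
                                 pooled_null = NULL) {
  dur <- diff(range(session$time))
  if (dur <= 2 * config$min_shift)
    stop("session must be longer than twice the minimum shift")
  vals <- variable_values(session, variable)
  if (is.matrix(vals)) stop("shuffle significance is one-dimensional")
  rate <- counts / 0.02
  obs <- modulation_scores(vals, rate)
  if (!is.finite(obs["score"]))
    return(list(score = NA_real_, side_scores = obs[c("below", "above")],
                significant = FALSE, symmetric = NA_character_,
                null = NULL, bounds = NULL))
  n <- length(counts); sr <- session$sample_rate
  min_k <- ceiling(config$min_shift * sr)
  null <- with_seed(config$seed, {
    ks <- sample(min_k:(n - min_k), config$n_shuffles, replace = TRUE)
    shifted_scores(vals, rate, ks)
  })
  null_pool <- if (identical(config$mode, "pooled") && !is.null(pooled_null))
    rbind(null, pooled_null) else null
  b2 <- stats::quantile(null_pool[, "score"], config$two_sided / 100,
                        na.rm = TRUE, names = FALSE)
  significant <- obs["score"] < b2[1] || obs["score"] > b2[2]
  sym <- NA_character_
  if (all(is.finite(obs[c("below", "above")]))) {
    lo_b <- stats::quantile(null_pool[, "below"], config$one_sided / 100,
                            na.rm = TRUE, names = FALSE)
    lo_a <- stats::quantile(null_pool[, "above"], config$one_sided / 100,
                            na.rm = TRUE, names = FALSE)
    if (obs["below"] < lo_b[1] && obs["above"] > lo_a[2]) sym <- "V"
    else if (obs["below"] > lo_b[2] && obs["above"] < lo_a[1]) sym <- "inverse-V"
  }
  list(score = unname(obs["score"]),
       side_scores = obs[c("below", "above")],
       bounds = b2, significant = unname(significant), symmetric = sym,
       null = null)
}
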