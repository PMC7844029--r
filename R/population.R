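#' Binomial test for direction preference
#'
#' Tests whether `k` of `n` cells preferring one direction departs from
#' an even split. The reported statistic is the continuity-corrected
#' normal approximation
#' `z = sign(k - n/2) * (|k - n/2| - 0.5) / (sqrt(n)/2)` (clamped to 0
#' when the half-count correction crosses the mean), and the p-value is
#' the exact two-sided binomial probability (doubled smaller tail,
#' capped at 1). This is the single convention supported; it reproduces
#' published worked examples self-consistently.
#'
#' @param k Number of successes (cells preferring the direction).
#' @param n Number of trials (cells tested).
#' @return An object of class `"binomial_preference_test"` with `k`,
#'   `n`, `z` and `p`.
#' @export
binomial_preference_test <- function(k, n) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  d <- k - n / 2
  z <- if (abs(d) <= 0.5) 0 else sign(d) * (abs(d) - 0.5) / (sqrt(n) / 2)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  structure(list(k = k, n = n, z = z, p = p),
            class = "binomial_preference_test")
}

#' @export
print.binomial_preference_test <- function(x, ...) {
  cat(sprintf("binomial preference test: %d/%d, Z = %.2f, P = %.3g\n",
              x$k, x$n, x$z, x$p))
  invisible(x)
}

#' Entropy of a binned sample (nats)
#'
#' `H = -sum_i P(X_i) log P(X_i)` over occupied bins, with empirical bin
#' probabilities and the natural logarithm. Also returns the entropy of
#' an equal-count uniform distribution of the same size and binning for
#' comparison.
#'
#' @param samples Numeric samples.
#' @param n_bins Number of equal-width bins over the sample range.
#' @return List with `entropy` and `uniform_entropy` (nats) and the bin
#'   `counts`.
#' @export
entropy <- function(samples, n_bins) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("empty input")
  counts <- bin_counts(samples, n_bins)
  list(entropy = entropy_from_counts(counts),
       uniform_entropy = log(n_bins),
       counts = counts)
}

bin_counts <- function(x, n_bins, rng = range(x)) {
  if (diff(rng) <= 0) return(c(length(x), rep(0L, n_bins - 1L)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(n_bins, pmax(1L, findInterval(x, edges, rightmost.closed = TRUE)))
  tabulate(idx, n_bins)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Mutual information between two binned variables (nats)
#'
#' `I(A, B) = sum_ij P(A_i, B_j) log[P(A_i, B_j) / (P(A_i) P(B_j))]`
#' with empirical probabilities. A shuffle null is built by permuting
#' one variable and recomputing.
#'
#' @param a,b Equal-length numeric vectors.
#' @param n_bins Bins per variable (scalar or length-2).
#' @param n_shuffles Number of permutations for the null (0 to skip).
#' @param seed Optional seed for the shuffle null.
#' @return List with `mi` (nats), `null` (shuffle values) and the
#'   marginal entropies `h_a`, `h_b`.
#' @export
mutual_information <- function(a, b, n_bins = 20, n_shuffles = 0,
                               seed = NULL) {
  if (length(a) != length(b)) stop("length mismatch")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(n_bins) == 1) n_bins <- c(n_bins, n_bins)
  ia <- bin_index(a, n_bins[1]); ib <- bin_index(b, n_bins[2])
  mi_of <- function(ia, ib) {
    joint <- tabulate((ia - 1L) * n_bins[2] + ib, n_bins[1] * n_bins[2])
    pj <- joint / sum(joint)
    pa <- tabulate(ia, n_bins[1]) / length(ia)
    pb <- tabulate(ib, n_bins[2]) / length(ib)
    pij <- pj[pj > 0]
    idx <- which(pj > 0) - 1L
    pa_i <- pa[idx %/% n_bins[2] + 1L]
    pb_j <- pb[idx %% n_bins[2] + 1L]
    sum(pij * log(pij / (pa_i * pb_j)))
  }
  mi <- mi_of(ia, ib)
  null <- NULL
  if (n_shuffles > 0)
    null <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
      mi_of(ia, sample(ib)), numeric(1)))
  list(mi = mi, null = null,
       h_a = entropy_from_counts(tabulate(ia, n_bins[1])),
       h_b = entropy_from_counts(tabulate(ib, n_bins[2])))
}

bin_index <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rep(1L, length(x)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pmin(n_bins, pmax(1L, findInterval(x, edges, rightmost.closed = TRUE)))
}

#' Permutation test for clustering of labels in tuning-curve space
#'
#' Each cell's tuning curve (one row of `curves`) is centered and scaled
#' to unit range, projected onto the first two principal components, and
#' the mean distance `d` of each labeled cell to its `k` nearest
#' same-label neighbors is compared with a null distribution obtained by
#' permuting the labels. `k` runs over `1..min(k_max, n_labeled - 1)`;
#' significance requires the Bonferroni-corrected bar `alpha / k_max`.
#'
#' @param curves n x m matrix of tuning curves (n cells, m bins).
#' @param labels Logical vector of length n: does the cell also encode
#'   the variable of interest?
#' @param k_max Maximum neighborhood size (default 10).
#' @param n_perm Number of label permutations (default 1000).
#' @param alpha Family-wise level before correction (default 0.05).
#' @param seed Optional seed.
#' @return An object of class `"clustering_test"`: per-`k` observed `d`,
#'   permutation `p`, the corrected threshold and verdict. If every
#'   point (or fewer than 2) is labeled the test is reported
#'   inapplicable.
#' @export
tuning_space_clustering_test <- function(curves, labels, k_max = 10,
                                         n_perm = 1000, alpha = 0.05,
                                         seed = NULL) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 5) stop("need >= 5 labeled points in tuning space")
  labels <- as.logical(labels)
  if (sum(labels) < 2) stop("fewer than 2 labeled points")
  X <- curves - rowMeans(curves)
  rng <- apply(X, 1, function(r) diff(range(r)))
  rng[rng == 0] <- 1
  X <- X / rng
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  Y <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  D <- as.matrix(stats::dist(Y))
  inapplicable <- all(labels)
  ks <- seq_len(max(1, min(k_max, sum(labels) - 1L)))
  kmax <- max(ks)
  mean_knn <- function(members) {
    sub <- D[members, members, drop = FALSE]
    diag(sub) <- Inf
    # one sort per row gives every k at once via cumulative means
    srt <- apply(sub, 1, function(r) sort.int(r)[seq_len(kmax)])
    srt <- matrix(srt, nrow = kmax)
    rowMeans(apply(srt, 2, cumsum) / ks)[ks]
  }
  d_obs <- mean_knn(which(labels))
  p <- rep(NA_real_, length(ks))
  if (!inapplicable) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        mean_knn(sample(n, sum(labels))), numeric(length(ks)))
    })
    perm <- matrix(perm, nrow = length(ks))
    p <- vapply(seq_along(ks), function(j) mean(perm[j, ] < d_obs[j]),
                numeric(1))
  }
  structure(list(k = ks, d = d_obs, p = p,
                 threshold = alpha / k_max,
                 significant = if (inapplicable) NA else any(p < alpha / k_max),
                 inapplicable = inapplicable, n_perm = n_perm,
                 projection = Y),
            class = "clustering_test")
}

#' @export
print.clustering_test <- function(x, ...) {
  if (x$inapplicable) {
    cat("clustering test inapplicable: all points share the label\n")
    return(invisible(x))
  }
  cat("tuning-space clustering test (", x$n_perm, " permutations)\n", sep = "")
  print(data.frame(k = x$k, d = signif(x$d, 4), p = x$p))
  cat(sprintf("significant at Bonferroni bar %.3g: %s\n",
              x$threshold, x$significant))
  invisible(x)
}
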