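#' Assemble the spline design matrix for a set of variables
#'
#' Builds per-variable cardinal-spline blocks (tensor products for 2-D
#' body position) and stacks them column-wise. Time bins are retained
#' only where every requested variable is finite, unmasked and inside its
#' percentile inclusion window; each variable's knots span exactly that
#' window, so every retained row of every block sums to 1. Rows also
#' carry a fold label: the time axis is cut into contiguous 10-s sections
#' allocated round-robin to 10 folds.
#'
#' @param session A [behavior_session()].
#' @param configs Named list of [variable_config()] objects (e.g. from
#'   [default_variable_configs()]); these define the candidate set and
#'   the joint inclusion mask.
#' @param min_bins Minimum retained bins (default 1000).
#' @param folds Number of cross-validation folds (default 10).
#' @param section_s Fold section length in seconds (default 10).
#' @return An object of class `"ln_design"`.
#' @export
assemble_design <- function(session, configs, min_bins = 1000,
                            folds = 10, section_s = 10) {
  stopifnot(inherits(session, "behavior_session"))
  Tn <- length(session$time)
  retained <- rep(TRUE, Tn)
  knots <- list()
  for (sym in names(configs)) {
    cfg <- configs[[sym]]
    vals <- variable_values(session, sym)
    msk <- Reduce(`&`, session$mask[cfg$channels], rep(TRUE, Tn))
    if (is.matrix(vals)) {
      kx <- resolve_knots(cfg, vals[msk, 1], axis = 1L)
      ky <- resolve_knots(cfg, vals[msk, 2], axis = 2L)
      knots[[sym]] <- list(x = kx, y = ky)
      ok <- msk & is.finite(vals[, 1]) & is.finite(vals[, 2]) &
        vals[, 1] >= kx[1] & vals[, 1] <= kx[length(kx)] &
        vals[, 2] >= ky[1] & vals[, 2] <= ky[length(ky)]
    } else {
      k <- resolve_knots(cfg, vals[msk])
      knots[[sym]] <- k
      ok <- msk & is.finite(vals)
      if (!cfg$circular) ok <- ok & vals >= k[1] & vals <= k[length(k)]
    }
    retained <- retained & ok
  }
  if (sum(retained) < min_bins)
    stop("insufficient data: only ", sum(retained), " retained bins")
  blocks <- list(); cols <- list(); p0 <- 0L
  for (sym in names(configs)) {
    cfg <- configs[[sym]]
    vals <- variable_values(session, sym)
    Xi <- if (is.matrix(vals))
      spline_design_2d(vals[retained, 1], vals[retained, 2],
                       knots[[sym]]$x, knots[[sym]]$y, s = cfg$s)
    else
      spline_design_1d(vals[retained], knots[[sym]], circular = cfg$circular,
                       period = cfg$period, s = cfg$s)
    blocks[[sym]] <- Xi
    cols[[sym]] <- p0 + seq_len(ncol(Xi))
    p0 <- p0 + ncol(Xi)
  }
  tt <- session$time[retained]
  fold <- (floor(tt / section_s) %% folds) + 1L
  structure(list(X = do.call(cbind, unname(blocks)), cols = cols,
                 knots = knots, configs = configs, retained = retained,
                 time = tt, fold = as.integer(fold), dt = 0.02,
                 arena = session$arena),
            class = "ln_design")
}

#' @export
print.ln_design <- function(x, ...) {
  cat(sprintf("<ln_design> %d retained bins x %d parameters (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(names(x$cols), collapse = ", ")))
  invisible(x)
}

# column indices of a variable subset
design_columns <- function(design, variables) {
  unlist(design$cols[variables], use.names = FALSE)
}

# compressed-sparse-row view of a design block (reused across folds)
as_csr <- function(X) {
  Xt <- Matrix::t(X)
  list(rp = Xt@p, ci = Xt@i, x = Xt@x, P = ncol(X), n = nrow(X))
}

# Penalized Poisson Newton fit. Maximizes
# sum(y * eta - exp(eta)) - beta * sum(w^2) with b0 unpenalized; the
# heavy lifting (gradient, Hessian accumulation, damped Newton steps)
# runs in compiled code on a CSR view of the design.
fit_penalized_poisson <- function(X = NULL, y, beta = 1, w0 = NULL,
                                  tol = 1e-6, max_iter = 100,
                                  csr = NULL, use = NULL) {
  if (is.null(csr)) {
    nc <- if (is.null(dim(X))) 0L else ncol(X)
    csr <- if (nc == 0L) list(P = 0L, n = length(y)) else as_csr(X)
  }
  if (is.null(use)) use <- rep(TRUE, csr$n)
  P <- csr$P
  ybar <- mean(y[use])
  if (P == 0L) {
    b0 <- log(max(ybar, 1e-12))
    return(list(coef = b0, kernel = sum(y[use] * b0 - exp(b0)),
                converged = TRUE, iter = 0L, grad_max = 0))
  }
  w <- if (is.null(w0)) c(log(max(ybar, 1e-12)), rep(0, P)) else w0
  res <- ln_newton_csr(csr$rp, csr$ci, csr$x, as.numeric(y), use,
                       2 * beta, w, tol, max_iter)
  list(coef = as.numeric(res$coef), kernel = res$kernel,
       converged = res$converged, iter = res$iter, grad_max = res$grad_max)
}

#' Fit a linear-nonlinear Poisson encoding model
#'
#' Maximizes the penalized Poisson log-likelihood
#' `sum(n_t log(lambda_t) - lambda_t) - beta * sum_i ||w_i||^2`, where
#' `log(lambda_t) = b0 + sum_i X_i(t) w_i` and `lambda_t` is the expected
#' spike count in the 20 ms bin `t`. The offset `b0` is unpenalized.
#' Optimization is by damped Newton iteration with the analytic gradient
#' and Hessian; the objective is concave, and convergence is declared at
#' gradient sup-norm `1e-6`.
#'
#' @param design An [assemble_design()] result, or a [behavior_session()]
#'   (in which case `configs` is used to build the design).
#' @param counts Integer spike counts per 20 ms bin, full session length
#'   (the design's retained mask is applied) or already restricted.
#' @param variables Character vector of variables to include; default all
#'   variables in the design. `character(0)` fits the mean-rate model.
#' @param beta L2 penalty hyperparameter (default 1).
#' @param configs Variable configurations, used only when `design` is a
#'   session.
#' @param warm_start Optional coefficient vector for warm starting.
#' @return An object of class `"ln_fit"` with components `b0`, `w`
#'   (named list of per-variable weight vectors), `variables`, `design`,
#'   `counts`, `beta` and convergence metadata.
#' @export
ln_fit <- function(design, counts, variables = NULL, beta = 1,
                   configs = NULL, warm_start = NULL) {
  if (inherits(design, "behavior_session")) {
    if (is.null(configs)) configs <- default_variable_configs(design)
    if (!is.null(variables)) configs <- configs[variables]
    design <- assemble_design(design, configs)
  }
  stopifnot(inherits(design, "ln_design"))
  if (is.null(variables)) variables <- names(design$cols)
  if (length(counts) == length(design$retained))
    counts <- counts[design$retained]
  if (length(counts) != nrow(design$X))
    stop("counts not aligned with design")
  cols <- design_columns(design, variables)
  X <- if (length(cols)) design$X[, cols, drop = FALSE] else NULL
  res <- fit_penalized_poisson(X, counts, beta = beta, w0 = warm_start)
  new_ln_fit(res, design, variables, counts, beta)
}

# assemble the classed fit object from a solver result
new_ln_fit <- function(res, design, variables, counts, beta) {
  coefs <- res$coef
  w <- list(); p0 <- 1L
  for (sym in variables) {
    k <- length(design$cols[[sym]])
    w[[sym]] <- coefs[p0 + seq_len(k)]
    p0 <- p0 + k
  }
  structure(list(b0 = coefs[1], w = w, coef_vector = coefs,
                 variables = variables, beta = beta,
                 design = design, counts = counts,
                 kernel = res$kernel, converged = res$converged,
                 iterations = res$iter, grad_max = res$grad_max,
                 dt = design$dt),
            class = "ln_fit")
}

# linear predictor (log expected count/bin) of an ln_fit on design rows
fit_eta <- function(fit, rows = NULL) {
  cols <- design_columns(fit$design, fit$variables)
  X <- fit$design$X[, cols, drop = FALSE]
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  as.numeric(fit$b0 + X %*% fit$coef_vector[-1])
}

#' @export
print.ln_fit <- function(x, ...) {
  cat("Linear-nonlinear Poisson encoding model\n")
  cat(sprintf("  variables: %s\n",
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(mean-rate model)"))
  cat(sprintf("  bins: %d   mean rate: %.2f spikes/s\n",
              length(x$counts), mean(x$counts) / x$dt))
  cat(sprintf("  b0 = %.3f   penalty beta = %g   converged: %s (%d iter)\n",
              x$b0, x$beta, x$converged, x$iterations))
  invisible(x)
}

#' @export
coef.ln_fit <- function(object, ...) {
  out <- object$coef_vector
  names(out) <- c("b0", unlist(lapply(object$variables, function(s)
    paste0(s, ".", seq_along(object$w[[s]])))))
  out
}

#' @export
logLik.ln_fit <- function(object, ...) {
  lam <- exp(fit_eta(object))
  val <- sum(stats::dpois(object$counts, lam, log = TRUE))
  structure(val, df = length(object$coef_vector), class = "logLik")
}

#' Predicted firing rate of an LN model
#'
#' @param object An [ln_fit()].
#' @param newdata Optional [behavior_session()]; the design is rebuilt
#'   with the fit's stored knots. Default: the training design.
#' @param type `"rate"` (spikes/s), `"count"` (expected spikes/bin) or
#'   `"log"` (log expected count/bin).
#' @param ... Unused.
#' @return Numeric vector over retained bins (with attribute `retained`
#'   when `newdata` is supplied).
#' @export
predict.ln_fit <- function(object, newdata = NULL,
                           type = c("rate", "count", "log"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- fit_eta(object)
  } else {
    nd <- rebuild_design(newdata, object$design, object$variables)
    eta <- as.numeric(object$b0 + nd$X %*% object$coef_vector[-1])
    attr(eta, "retained") <- nd$retained
  }
  switch(type, log = eta, count = exp(eta), rate = exp(eta) / object$dt)
}

# rebuild a design on new data with frozen knots (for predict/stability)
rebuild_design <- function(session, design, variables) {
  Tn <- length(session$time)
  retained <- rep(TRUE, Tn)
  blocks <- list()
  for (sym in variables) {
    cfg <- design$configs[[sym]]
    vals <- variable_values(session, sym)
    msk <- Reduce(`&`, session$mask[cfg$channels], rep(TRUE, Tn))
    k <- design$knots[[sym]]
    if (is.matrix(vals)) {
      ok <- msk & is.finite(vals[, 1]) & is.finite(vals[, 2]) &
        vals[, 1] >= k$x[1] & vals[, 1] <= k$x[length(k$x)] &
        vals[, 2] >= k$y[1] & vals[, 2] <= k$y[length(k$y)]
    } else {
      ok <- msk & is.finite(vals)
      if (!cfg$circular) ok <- ok & vals >= k[1] & vals <= k[length(k)]
    }
    retained <- retained & ok
  }
  for (sym in variables) {
    cfg <- design$configs[[sym]]
    vals <- variable_values(session, sym)
    k <- design$knots[[sym]]
    blocks[[sym]] <- if (is.matrix(vals))
      spline_design_2d(vals[retained, 1], vals[retained, 2], k$x, k$y,
                       s = cfg$s)
    else
      spline_design_1d(vals[retained], k, circular = cfg$circular,
                       period = cfg$period, s = cfg$s)
  }
  list(X = do.call(cbind, unname(blocks)), retained = retained)
}

#' @export
residuals.ln_fit <- function(object, type = c("pearson", "deviance", "response"),
                             ...) {
  type <- match.arg(type)
  lam <- exp(fit_eta(object))
  y <- object$counts
  switch(type,
         response = y - lam,
         pearson = (y - lam) / sqrt(lam),
         deviance = {
           d <- 2 * (ifelse(y > 0, y * log(y / lam), 0) - (y - lam))
           sign(y - lam) * sqrt(pmax(d, 0))
         })
}

#' Simulate spike trains from a fitted LN model
#'
#' Draws Poisson counts from the fitted per-bin rate; the generative
#' counterpart of [ln_fit()], used e.g. to regenerate spike trains with
#' selected variables ablated.
#'
#' @param object An [ln_fit()].
#' @param nsim Number of replicate trains.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Integer vector (or matrix with `nsim` columns) of counts over
#'   the design's retained bins.
#' @export
simulate.ln_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lam <- exp(fit_eta(object))
  with_seed(seed, {
    if (nsim == 1) as.integer(stats::rpois(length(lam), lam))
    else matrix(stats::rpois(nsim * length(lam), rep(lam, nsim)),
                ncol = nsim)
  })
}

#' @export
summary.ln_fit <- function(object, ...) {
  lam <- exp(fit_eta(object))
  out <- list(variables = object$variables,
              n_bins = length(object$counts),
              mean_rate = mean(object$counts) / object$dt,
              deviance = -2 * (object$kernel -
                                 sum(object$counts * log(pmax(object$counts, 1)) -
                                       object$counts)),
              converged = object$converged,
              w_norms = vapply(object$w, function(w) sqrt(sum(w^2)),
                               numeric(1)))
  class(out) <- "summary.ln_fit"
  out
}

#' @export
print.summary.ln_fit <- function(x, ...) {
  cat("LN Poisson model:", paste(x$variables, collapse = " + "), "\n")
  cat(sprintf("  %d bins, mean rate %.2f spikes/s, deviance %.1f\n",
              x$n_bins, x$mean_rate, x$deviance))
  cat("  ||w_i||:", paste(sprintf("%s=%.2f", names(x$w_norms), x$w_norms),
                          collapse = "  "), "\n")
  invisible(x)
}

#' Cross-validated model performance (log-likelihood increase)
#'
#' 10-fold cross-validation over contiguous 10-s sections allocated
#' round-robin to folds. For each fold the model is refit on the other
#' nine and scored on the held-out bins as the increase in Poisson
#' log-likelihood over the training-set mean-rate model, reported both
#' raw (nats) and normalized per held-out spike (bits/spike).
#'
#' @param design An [ln_design]. @param counts Spike counts.
#' @param variables Variables of the model under evaluation.
#' @param beta Penalty. @param warm Optional full-data [ln_fit()], or a
#'   coefficient vector, used to warm-start the full fit.
#' @return List with `lli` (nats per fold), `lli_per_spike`
#'   (bits/spike per fold), `fold_fits` (coefficient vectors), and the
#'   full-data `fit`.
#' @export
crossvalidate <- function(design, counts, variables = NULL, beta = 1,
                          warm = NULL) {
  stopifnot(inherits(design, "ln_design"))
  if (is.null(variables)) variables <- names(design$cols)
  if (length(counts) == length(design$retained))
    counts <- counts[design$retained]
  folds <- sort(unique(design$fold))
  if (length(folds) < 2) stop("empty fold: session too short for CV")
  if (diff(range(design$time)) < 100)
    stop("session must cover >= 100 s for 10-fold CV")
  cols <- design_columns(design, variables)
  empty <- length(cols) == 0L
  X <- if (empty) NULL else design$X[, cols, drop = FALSE]
  csr <- if (empty) list(P = 0L, n = length(counts)) else as_csr(X)
  w0 <- if (inherits(warm, "ln_fit")) warm$coef_vector else warm
  res_full <- fit_penalized_poisson(y = counts, beta = beta, w0 = w0,
                                    csr = csr)
  full <- if (inherits(warm, "ln_fit")) warm
          else new_ln_fit(res_full, design, variables, counts, beta)
  lli <- numeric(length(folds)); llin <- numeric(length(folds))
  fold_coefs <- vector("list", length(folds))
  for (f in folds) {
    test <- design$fold == f
    if (!any(test) || all(test)) stop("empty fold")
    ytr <- counts[!test]; yte <- counts[test]
    res <- fit_penalized_poisson(y = counts, beta = beta,
                                 w0 = res_full$coef,
                                 csr = csr, use = !test)
    eta_all <- if (!empty) as.numeric(res$coef[1] + X %*% res$coef[-1])
               else rep(res$coef[1], length(counts))
    eta_te <- eta_all[test]
    lam0 <- max(mean(ytr), 1e-12)
    ll_model <- sum(yte * eta_te - exp(pmin(eta_te, 30)))
    ll_mean <- sum(yte * log(lam0) - lam0)
    lli[f] <- ll_model - ll_mean
    llin[f] <- if (sum(yte) > 0) (ll_model - ll_mean) / sum(yte) / log(2)
               else NA_real_
    fold_coefs[[f]] <- res$coef
  }
  list(lli = lli, lli_per_spike = llin, fold_fits = fold_coefs, fit = full)
}

#' Forward selection of encoded variables
#'
#' The heuristic forward-search procedure: fit every single-variable
#' model and keep the best by mean held-out log-likelihood increase
#' (LLI); iteratively add the best-scoring additional variable while a
#' one-sided Wilcoxon signed-rank test on the 10 fold-paired LLIs rejects
#' at `alpha`; finally require the selected model to beat the mean-rate
#' baseline with the same test, otherwise the cell is classified as
#' encoding nothing. Ties in mean LLI break lexicographically by symbol.
#'
#' @param session A [behavior_session()] (or a prebuilt [ln_design]).
#' @param counts Spike counts per 20 ms bin.
#' @param configs Candidate [variable_config()] list (>= 2 candidates);
#'   default [default_variable_configs()].
#' @param alpha Signed-rank significance level (default 0.05).
#' @param beta L2 penalty.
#' @param min_bins Passed to [assemble_design()].
#' @return An object of class `"ln_select"`: `selected` (character,
#'   possibly empty), `steps` (per-step candidate LLI summaries and
#'   p-values), `final_p` (final-vs-baseline p-value), `cv` (the selected
#'   model's cross-validation), `fit` (full-data fit of the selected
#'   model, or NULL), and the design.
#' @export
forward_select <- function(session, counts, configs = NULL, alpha = 0.05,
                           beta = 1, min_bins = 1000) {
  if (inherits(session, "ln_design")) {
    design <- session
  } else {
    if (is.null(configs)) configs <- default_variable_configs(session)
    design <- assemble_design(session, configs, min_bins = min_bins)
  }
  candidates <- sort(names(design$cols))
  if (length(candidates) < 2) stop("need >= 2 candidate variables")
  if (length(counts) == length(design$retained))
    counts <- counts[design$retained]
  selected <- character(0)
  current_cv <- NULL
  steps <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    cand_cv <- lapply(remaining, function(v) {
      vars <- c(selected, v)
      # warm-start from the current model: zeros for the new variable
      warm <- NULL
      if (!is.null(current_cv)) {
        cur <- current_cv$fit
        warm <- c(cur$b0, unlist(lapply(vars, function(s)
          cur$w[[s]] %||% rep(0, length(design$cols[[s]])))))
      }
      tryCatch(crossvalidate(design, counts, vars, beta = beta, warm = warm),
               error = function(e) NULL)
    })
    names(cand_cv) <- remaining
    ok <- !vapply(cand_cv, is.null, logical(1))
    if (!any(ok)) break
    means <- vapply(cand_cv[ok], function(z) mean(z$lli), numeric(1))
    best <- names(means)[which.max(means)]   # lexicographic tie-break via sort
    step <- list(candidates = remaining,
                 lli = lapply(cand_cv[ok], `[[`, "lli"),
                 mean_lli = means, best = best, p = NA_real_,
                 failed = remaining[!ok])
    if (is.null(current_cv)) {
      accepted <- TRUE
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(cand_cv[[best]]$lli, current_cv$lli,
                           paired = TRUE, alternative = "greater",
                           exact = TRUE)$p.value)
      step$p <- p
      accepted <- is.finite(p) && p < alpha
    }
    steps[[length(steps) + 1L]] <- step
    if (!accepted) break
    selected <- c(selected, best)
    current_cv <- cand_cv[[best]]
  }
  final_p <- NA_real_
  if (!is.null(current_cv)) {
    final_p <- suppressWarnings(
      stats::wilcox.test(current_cv$lli, alternative = "greater",
                         exact = TRUE)$p.value)
    if (!(is.finite(final_p) && final_p < alpha)) {
      selected <- character(0)
    }
  }
  fit <- if (length(selected)) current_cv$fit else NULL
  structure(list(selected = selected, steps = steps, final_p = final_p,
                 cv = if (length(selected)) current_cv else NULL,
                 fit = fit, design = design, counts = counts,
                 alpha = alpha, beta = beta),
            class = "ln_select")
}

#' @export
print.ln_select <- function(x, ...) {
  cat("Forward selection of LN model variables\n")
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = " + "), "\n")
    cat(sprintf("  mean held-out LLI: %.2f nats (%.3f bits/spike)\n",
                mean(x$cv$lli), mean(x$cv$lli_per_spike, na.rm = TRUE)))
    cat(sprintf("  final vs mean-rate baseline: p = %.3g\n", x$final_p))
  } else {
    cat("  no significant tuning to any candidate variable\n")
  }
  invisible(x)
}

#' @export
summary.ln_select <- function(object, ...) {
  steps <- lapply(seq_along(object$steps), function(i) {
    s <- object$steps[[i]]
    data.frame(step = i, best = s$best,
               mean_lli = s$mean_lli[s$best],
               p = s$p, row.names = NULL)
  })
  out <- list(selected = object$selected,
              path = do.call(rbind, steps), final_p = object$final_p)
  class(out) <- "summary.ln_select"
  out
}

#' @export
print.summary.ln_select <- function(x, ...) {
  cat("Selection path:\n")
  print(x$path, row.names = FALSE)
  cat("final-vs-baseline p:", format(x$final_p, digits = 3), "\n")
  cat("selected:", if (length(x$selected))
    paste(x$selected, collapse = " + ") else "(none)", "\n")
  invisible(x)
}

#' Plot model-derived tuning curves of a selected model
#'
#' @param x An [ln_select()] with a non-empty selected set.
#' @param variables Variables to plot (default: all selected 1-D ones).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ln_select <- function(x, variables = NULL, ...) {
  if (!length(x$selected)) {
    graphics::plot.new(); graphics::title("no significant tuning")
    return(invisible(x))
  }
  vars <- variables %||% x$selected
  vars <- vars[vars != "B" | x$design$arena$kind != "open_field"]
  if (!length(vars)) return(invisible(x))
  op <- graphics::par(mfrow = c(1, length(vars)))
  on.exit(graphics::par(op), add = TRUE)
  for (v in vars) {
    tc <- model_tuning_curve(x$fit, v, cv = x$cv)
    plot(tc, ...)
  }
  invisible(x)
}
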