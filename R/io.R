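#' Write and read behavior sessions as delimited tables
#'
#' Tab-separated text with one `time` column and one column per channel,
#' headed by the variable symbols (`B_x, B_y, B_s, H_a, H_p, H_r, dH_a,
#' dH_p, dH_r, E_h, E_v, dE_h, dE_v`). Masked samples are written as NA;
#' a comment line preserves the arena geometry and sampling rate, so a
#' write-read round trip is lossless.
#'
#' @param session A [behavior_session()].
#' @param path Output file.
#' @return `write_behavior` returns `path` invisibly; `read_behavior`
#'   returns a [behavior_session()].
#' @export
write_behavior <- function(session, path) {
  df <- as.data.frame(session)
  for (nm in names(session$channels))
    df[[nm]][!session$mask[[nm]]] <- NA
  a <- session$arena
  hdr <- if (identical(a$kind, "open_field"))
    sprintf("# arena=open_field width=%g height=%g rate=%g",
            a$width, a$height, session$sample_rate)
  else
    sprintf("# arena=vr_track length=%g n_landmarks=%g rate=%g",
            a$length, a$n_landmarks %||% 0, session$sample_rate)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#")) stop("header mismatch: missing arena comment line")
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  meta <- stats::setNames(
    lapply(kv, function(s) strsplit(s, "=")[[1]][2]),
    vapply(kv, function(s) strsplit(s, "=")[[1]][1], character(1)))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!"time" %in% names(df)) stop("header mismatch: no time column")
  if (any(diff(df$time) <= 0)) stop("non-monotone time axis")
  arena <- if (identical(meta$arena, "open_field"))
    list(kind = "open_field", width = as.numeric(meta$width),
         height = as.numeric(meta$height))
  else
    list(kind = "vr_track", length = as.numeric(meta$length),
         n_landmarks = as.numeric(meta$n_landmarks))
  chans <- df[setdiff(names(df), "time")]
  mask <- lapply(chans, function(v) !is.na(v))
  behavior_session(df$time, as.list(chans), mask,
                   sample_rate = as.numeric(meta$rate), arena = arena)
}

#' Write and read spike-count tables
#'
#' Per-cell integer-count columns aligned row-for-row with the behavior
#' table.
#'
#' @param counts Integer vector or T x n_cells matrix.
#' @param path File path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes`
#'   returns an integer matrix with one column per cell.
#' @export
write_spikes <- function(counts, path) {
  m <- as.matrix(counts)
  if (is.null(colnames(m))) colnames(m) <- paste0("cell_", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (any(m != round(m) | m < 0, na.rm = TRUE))
    stop("unit violation: spike counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m
}

#' Serialize ground-truth cells and model fits as JSON
#'
#' @param cell A [ground_truth_cell()]; `fit` an [ln_fit()].
#' @param path Output file.
#' @return The path, invisibly; readers return the reconstructed object.
#' @export
write_cell_json <- function(cell, path) {
  jsonlite::write_json(list(bias = cell$bias,
                            tuning = lapply(cell$tuning, unclass)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_json
#' @export
read_cell_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tuning <- lapply(doc$tuning, function(t) {
    t$coefs <- unlist(t$coefs); t$range <- unlist(t$range)
    structure(t, class = "gt_tuning")
  })
  ground_truth_cell(doc$bias, tuning)
}

#' @rdname write_cell_json
#' @param fit An [ln_fit()].
#' @export
write_ln_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(b0 = fit$b0, beta = fit$beta, variables = fit$variables,
         weights = fit$w, knots = fit$design$knots[fit$variables],
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an aligned behavior + spikes session from disk
#'
#' Validates alignment and units and logs a coverage report; sessions
#' where less than 70% of the position bins were visited get a warning
#' mirroring the conventional inclusion rule.
#'
#' @param behavior_path Behavior table from [write_behavior()].
#' @param spikes_path Spike table from [write_spikes()].
#' @return List with `session`, `counts` and `coverage`.
#' @export
load_session <- function(behavior_path, spikes_path) {
  session <- read_behavior(behavior_path)
  counts <- read_spikes(spikes_path)
  if (nrow(counts) != length(session$time))
    stop("alignment error: spike table has ", nrow(counts),
         " rows but behavior has ", length(session$time))
  cov <- position_coverage(session)
  if (cov < 0.7)
    warning(sprintf(
      "session covered only %.0f%% of position bins (< 70%%): conventionally excluded from model fitting",
      100 * cov))
  list(session = session, counts = counts, coverage = cov)
}
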