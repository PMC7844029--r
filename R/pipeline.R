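#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run: dataset kind, session
#' length, candidate variables, model hyperparameters and seeds. The
#' resolved configuration travels with the result bundle, and every
#' output carries its MD5 hash.
#'
#' @param kind `"open_field"` or `"vr_track"`.
#' @param session_length Seconds (default 1200).
#' @param n_cells Number of simulated cells when `cells` is NULL.
#' @param cells Optional list of [ground_truth_cell()] objects.
#' @param s Spline tension. @param beta L2 penalty. @param alpha
#'   Selection level. @param seed Master seed.
#' @param arena Optional overrides for [behavior_spec()] geometry.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(kind = c("open_field", "vr_track"),
                            session_length = 1200, n_cells = 5,
                            cells = NULL, s = 0.6, beta = 1, alpha = 0.05,
                            seed = 1, arena = list()) {
  kind <- match.arg(kind)
  stopifnot(session_length >= 100, n_cells >= 1 || !is.null(cells),
            s >= 0.5, s <= 0.7, beta >= 0, alpha > 0, alpha < 1)
  structure(list(kind = kind, session_length = session_length,
                 n_cells = if (is.null(cells)) n_cells else length(cells),
                 cells = cells, s = s, beta = beta, alpha = alpha,
                 seed = as.integer(seed), arena = arena),
            class = "pipeline_config")
}

#' Example ground-truth cell population
#'
#' A mixture typical of the recorded populations: position cells,
#' conjunctive cells adding a second variable (head direction, pitch,
#' roll or azimuthal velocity in the open field; speed or eye variables
#' on the track), and untuned cells.
#'
#' @param kind Dataset kind. @param n Number of cells. @param seed Seed.
#' @param arena Arena geometry list (width/height or length).
#' @return List of [ground_truth_cell()] objects.
#' @export
example_cells <- function(kind = "open_field", n = 5, seed = 1,
                          arena = list(width = 50, height = 50, length = 400)) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kindi <- (i - 1L) %% 5L
      if (kind == "open_field") {
        place <- tuning_place2d(stats::runif(1, 10, arena$width - 10),
                                stats::runif(1, 10, arena$height - 10),
                                sigma = stats::runif(1, 6, 10),
                                amp = stats::runif(1, 1.5, 2.5))
        extra <- switch(kindi + 1L,
          NULL,
          list(H_a = tuning_vonmises(stats::runif(1, 0, 360),
                                     kappa = stats::runif(1, 0.8, 1.5))),
          list(H_p = tuning_poly(c(stats::runif(1, 0.8, 1.4), 0), c(-30, 60))),
          list(H_r = tuning_poly(c(stats::runif(1, 0.9, 1.5), 0, 0), c(-50, 50))),
          list(dH_a = tuning_rectified(stats::runif(1, 0.004, 0.007))))
        ground_truth_cell(log(0.1), c(list(B = place), extra))
      } else {
        place <- tuning_place1d(stats::runif(1, 0, arena$length),
                                sigma = stats::runif(1, 25, 45),
                                amp = stats::runif(1, 1.5, 2.5),
                                period = arena$length)
        extra <- switch(kindi + 1L,
          NULL,
          list(B_s = tuning_linear(stats::runif(1, 0.02, 0.04), center = 15)),
          list(E_h = tuning_poly(c(stats::runif(1, 0.8, 1.2), 0), c(-3, 3))),
          list(E_v = tuning_poly(c(stats::runif(1, 0.9, 1.4), 0, 0), c(-2, 2))),
          list(dE_h = tuning_linear(stats::runif(1, 0.25, 0.4))))
        ground_truth_cell(log(0.1), c(list(B = place), extra))
      }
    })
  })
}

#' Run the end-to-end analysis pipeline on synthetic data
#'
#' Simulates a behavior session and ground-truth spike trains, runs
#' forward selection per cell, derives model and raw tuning curves,
#' stability, shape and velocity-subtype classifications and variable
#' contributions, and computes population statistics. Fully
#' deterministic under the config seed; the result bundle carries the
#' config hash and per-stage checksums.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"ln_pipeline_result"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  arena <- config$arena
  spec <- if (config$kind == "open_field")
    behavior_spec("open_field", config$session_length,
                  width = arena$width %||% 50, height = arena$height %||% 50,
                  seed = config$seed)
  else
    behavior_spec("vr_track", config$session_length,
                  track_length = arena$length %||% 400, seed = config$seed)
  session <- if (config$kind == "open_field")
    simulate_open_field_behavior(spec) else simulate_vr_behavior(spec)
  cells <- config$cells %||% example_cells(
    config$kind, config$n_cells, seed = config$seed + 1L,
    arena = list(width = spec$width, height = spec$height,
                 length = spec$track_length))
  counts <- vapply(seq_along(cells), function(i)
    generate_ln_spikes(cells[[i]], session, seed = config$seed + 100L + i),
    integer(length(session$time)))
  colnames(counts) <- paste0("cell_", seq_along(cells))
  configs <- default_variable_configs(session, s = config$s)
  design <- assemble_design(session, configs)
  selections <- lapply(seq_along(cells), function(i)
    forward_select(design, counts[, i], alpha = config$alpha,
                   beta = config$beta))
  rows <- list()
  for (i in seq_along(cells)) {
    sel <- selections[[i]]
    if (!length(sel$selected)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = i, variable = "none", selected = FALSE, degree = NA,
        subtype = NA, direction = NA, stability = NA, contribution = NA,
        mean_lli_bits_per_spike = NA)
      next
    }
    for (v in sel$selected) {
      is2d <- v == "B" && config$kind == "open_field"
      deg <- sub <- dir <- NA; stab <- NA; contrib <- NA
      if (!is2d) {
        tc <- model_tuning_curve(sel$fit, v, cv = sel$cv)
        sh <- classify_shape(tc)
        deg <- sh$degree; dir <- sh$direction
        if (grepl("^d", v) && tc$range[1] < 0 && tc$range[2] > 0) {
          sub <- tryCatch(classify_velocity_subtype(tc, sh)$subtype,
                          error = function(e) NA_character_)
        }
        stab <- tryCatch(
          tuning_stability(session, counts[, i], sel$selected, v,
                           configs = configs, beta = config$beta),
          error = function(e) NA_real_)
      }
      if (length(sel$selected) >= 2)
        contrib <- variable_contribution(sel, v)$contribution
      rows[[length(rows) + 1L]] <- data.frame(
        cell = i, variable = v, selected = TRUE, degree = deg,
        subtype = sub, direction = dir, stability = stab,
        contribution = contrib,
        mean_lli_bits_per_spike = mean(sel$cv$lli_per_spike, na.rm = TRUE))
    }
  }
  summary_tab <- do.call(rbind, rows)
  pref <- NULL
  by_var <- split(summary_tab[summary_tab$selected & !is.na(summary_tab$direction), ],
                  summary_tab$variable[summary_tab$selected & !is.na(summary_tab$direction)])
  pref <- do.call(rbind, lapply(names(by_var), function(v) {
    tb <- by_var[[v]]
    bt <- binomial_preference_test(sum(tb$direction == "positive"), nrow(tb))
    data.frame(variable = v, k = bt$k, n = bt$n, z = bt$z, p = bt$p)
  }))
  manifest <- list(
    seed = config$seed,
    config_hash = object_md5(unclass(config)),
    r_version = as.character(getRversion()),
    checksums = list(session = object_md5(session),
                     counts = object_md5(counts),
                     selection = object_md5(lapply(selections, `[[`, "selected")),
                     summary = object_md5(summary_tab)))
  structure(list(config = config, session = session, cells = cells,
                 counts = counts, selections = selections,
                 summary = summary_tab, preference_tests = pref,
                 manifest = manifest),
            class = "ln_pipeline_result")
}

#' @export
print.ln_pipeline_result <- function(x, ...) {
  cat(sprintf("<ln_pipeline_result> %s, %d cells, seed %d (config %s)\n",
              x$config$kind, length(x$cells), x$config$seed,
              substr(x$manifest$config_hash, 1, 8)))
  sel <- vapply(x$selections, function(s)
    if (length(s$selected)) paste(s$selected, collapse = "+") else "none",
    character(1))
  cat("  selected sets:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline result bundle to a directory
#'
#' Long-format TSV for the summary and preference tables, JSON for the
#' manifest and per-cell fits, behavior/spikes as delimited tables.
#' Every table carries the config hash in a comment line.
#'
#' @param result An [run_pipeline()] result. @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("# config_hash=", result$manifest$config_hash)
  wr <- function(df, file) {
    con <- file(file.path(dir, file), "w"); on.exit(close(con), add = TRUE)
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(result$summary, "summary.tsv")
  if (!is.null(result$preference_tests))
    wr(result$preference_tests, "preference_tests.tsv")
  write_behavior(result$session, file.path(dir, "behavior.tsv"))
  write_spikes(result$counts, file.path(dir, "spikes.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(result$selections)) {
    s <- result$selections[[i]]
    if (length(s$selected))
      write_ln_fit_json(s$fit, file.path(dir, sprintf("fit_cell_%03d.json", i)))
  }
  invisible(dir)
}
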