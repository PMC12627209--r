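# File-level pipeline: configuration, simulate / analyze / fit / recover.
# Each command writes its outputs plus a config snapshot so a run is fully
# reproducible from (config, seed).

#' Build a run configuration
#'
#' All documented defaults are explicit in the returned list, which
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param ... Named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return A named list of class `ffr_config`.
#' @export
ffr_config <- function(...) {
  cfg <- list(
    n_hues = 48L,
    jnd_per_step = 1,
    n_observers = 1L,
    n_trials = 450L,
    offset_probabilities = rep(1 / 15, 15),
    conditions = ffr_conditions(),
    model = list(type = "subsampling", N = 30L, sigma = 5,
                 response_noise_sd = 0.5),
    analysis = list(per_trial = TRUE, davies_k = 10L,
                    alternative = "two.sided"),
    fit = list(sigma_lower = 0.05, sigma_upper = 20, sigma_tol = 1e-3,
               eps = 1e-12),
    recovery = list(n_runs = 400L, trials_per_run = 450L,
                    N_range = c(1L, 36L), sigma_range = c(0.5, 10)),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) {
      ffr_stop(sprintf("unknown config field: %s", nm), "ffr_config_error")
    }
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (sub in names(dots[[nm]])) {
        if (!sub %in% names(cfg[[nm]])) {
          ffr_stop(sprintf("unknown config field: %s.%s", nm, sub),
                   "ffr_config_error")
        }
        cfg[[nm]][[sub]] <- dots[[nm]][[sub]]
      }
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- c("ffr_config", "list")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!all(cfg$conditions %in% ffr_conditions())) {
    bad <- setdiff(cfg$conditions, ffr_conditions())
    ffr_stop(sprintf("config field `conditions` has invalid distribution name(s): %s",
                     paste(bad, collapse = ", ")),
             "ffr_config_error")
  }
  if (!cfg$model$type %in% c("subsampling", "veridical", "none")) {
    ffr_stop(sprintf("config field `model.type` must be one of subsampling, veridical, none; got '%s'",
                     cfg$model$type),
             "ffr_config_error")
  }
  if (length(cfg$offset_probabilities) != 15) {
    ffr_stop("config field `offset_probabilities` must have 15 entries",
             "ffr_config_error")
  }
  invisible(cfg)
}

config_wheel <- function(cfg) color_wheel(cfg$n_hues, cfg$jnd_per_step)

config_model <- function(cfg) {
  switch(cfg$model$type,
    subsampling = subsampling_params(cfg$model$N, cfg$model$sigma),
    veridical = veridical_params(cfg$model$response_noise_sd),
    none = NULL
  )
}

#' Write / read a configuration as JSON
#'
#' @param cfg An [ffr_config()] list.
#' @param path JSON file path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ffr_stop(sprintf("config file not found: %s", path), "ffr_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ffr_config, raw)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Simulate sessions to disk
#'
#' Generates `n_observers` sessions, fills responses with the configured
#' observer model (unless `model.type` is `"none"`), and writes
#' `session.csv` plus a `config.json` snapshot to `out_dir`. Identical
#' configurations produce byte-identical output.
#'
#' @param cfg An [ffr_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the session data frame and file paths.
#' @export
ffr_simulate <- function(cfg = ffr_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wheel <- config_wheel(cfg)
  model <- config_model(cfg)
  sessions <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_observers), function(o) {
      s <- generate_session(cfg$n_trials,
                            observer_id = sprintf("obs%02d", o),
                            wheel = wheel,
                            offset_prob = cfg$offset_probabilities,
                            conditions = cfg$conditions)
      if (!is.null(model)) s <- simulate_dataset(s, model, wheel = wheel)
      s
    })
  })
  session <- do.call(rbind, lapply(sessions, as.data.frame))
  attr(session, "wheel") <- wheel
  class(session) <- c("ffr_session", "data.frame")
  session_path <- file.path(out_dir, "session.csv")
  write_session(session, session_path)
  config_path <- file.path(out_dir, "config.json")
  write_config(cfg, config_path)
  message(sprintf("ffr_simulate: wrote %d trial(s) for %d observer(s) to %s",
                  nrow(session), cfg$n_observers, session_path))
  invisible(list(session = session, session_path = session_path,
                 config_path = config_path))
}

#' Analyze a session: folded curves, paired tests, segmented fits
#'
#' Runs the descriptive and segmented-regression analyses on a completed
#' session: folded per-observer curves, condition-level aggregates with
#' SEM, mean-vs-offset paired t-tests, a broken-line fit per condition on
#' the aggregated data (per-trial responses by default), and per-observer
#' slopes at each condition's aggregated break point with group t-tests.
#'
#' @param session An `ffr_session` data frame or the path to a session CSV.
#' @param out_dir Optional output directory; when given, writes
#'   `folded_curves.csv`, `aggregated_curves.csv`,
#'   `mean_vs_offset_tests.csv`, `broken_line_fits.json`,
#'   `individual_slopes.csv` and `group_slope_tests.csv`.
#' @param per_trial Fit the aggregated broken line to per-trial responses
#'   (default) or to per-observer offset means.
#' @param davies_k Candidate count for the Davies test.
#' @return A list with elements `folded`, `aggregated`, `mean_tests`,
#'   `broken_line` (per condition), `individual_slopes`, `group_tests`.
#' @export
ffr_analyze <- function(session, out_dir = NULL, per_trial = TRUE,
                        davies_k = 10L) {
  if (is.character(session)) session <- read_session(session)
  validate_session(session, require_responses = TRUE)
  folded <- fold_and_average(session)
  multi <- length(unique(session$observer_id)) >= 2
  aggregated <- if (multi) aggregate_curves(folded) else NULL
  mean_tests <- if (multi) compare_mean_vs_offsets(folded) else NULL

  conds <- intersect(ffr_conditions(), unique(session$condition))
  broken <- list()
  slopes <- list()
  gtests <- list()
  for (cond in conds) {
    if (per_trial) {
      sub <- session[session$condition == cond, ]
      x <- abs(sub$test_offset); y <- sub$response
    } else {
      sub <- folded[folded$condition == cond, ]
      x <- sub$abs_offset; y <- sub$mean_response
    }
    broken[[cond]] <- fit_broken_line(x, y, davies_k = davies_k)
    psi <- broken[[cond]]$psi
    for (obs in unique(session$observer_id)) {
      osub <- session[session$condition == cond &
                        session$observer_id == obs, ]
      sl <- slopes_at_fixed_break(abs(osub$test_offset), osub$response, psi)
      slopes[[length(slopes) + 1L]] <- data.frame(
        observer_id = obs, condition = cond, psi = psi,
        b1 = sl[["b1"]], b2 = sl[["b2"]], stringsAsFactors = FALSE)
    }
    if (multi) {
      sdf <- do.call(rbind, slopes)
      sdf <- sdf[sdf$condition == cond, ]
      for (seg in c("b1", "b2")) {
        gt <- group_slope_test(sdf[[seg]])
        gtests[[length(gtests) + 1L]] <- data.frame(
          condition = cond, segment = seg, t = gt$t, df = gt$df, p = gt$p,
          cohens_d = gt$cohens_d, note = gt$note, stringsAsFactors = FALSE)
      }
    }
  }
  individual_slopes <- do.call(rbind, slopes)
  group_tests <- if (length(gtests)) do.call(rbind, gtests) else NULL

  out <- list(folded = folded, aggregated = aggregated,
              mean_tests = mean_tests, broken_line = broken,
              individual_slopes = individual_slopes,
              group_tests = group_tests)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(folded, file.path(out_dir, "folded_curves.csv"),
              row.names = FALSE)
    if (multi) {
      write.csv(aggregated, file.path(out_dir, "aggregated_curves.csv"),
                row.names = FALSE)
      write.csv(mean_tests, file.path(out_dir, "mean_vs_offset_tests.csv"),
                row.names = FALSE)
      write.csv(group_tests, file.path(out_dir, "group_slope_tests.csv"),
                row.names = FALSE)
    }
    write.csv(individual_slopes, file.path(out_dir, "individual_slopes.csv"),
              row.names = FALSE)
    fits_json <- lapply(broken, function(f) {
      f <- unclass(f)
      f[c("psi", "ci_psi", "intercept", "b1", "b2", "ci_b1", "ci_b2",
          "davies_p", "rss", "n", "iter", "converged")]
    })
    write_json_stable(fits_json, file.path(out_dir, "broken_line_fits.json"))
  }
  invisible(out)
}

#' Fit the sub-sampling model per observer, with file output
#'
#' @param session An `ffr_session` data frame or a session CSV path.
#' @param out Optional JSON output path; a per-observer CSV with the same
#'   stem is written next to it.
#' @param ... Passed to [fit_mle()].
#' @return Invisibly, a named list of `ffr_fit` objects (one per observer).
#' @export
ffr_fit <- function(session, out = NULL, ...) {
  if (is.character(session)) session <- read_session(session)
  validate_session(session, require_responses = TRUE)
  observers <- unique(session$observer_id)
  fits <- lapply(observers, function(obs) {
    fit_mle(session[session$observer_id == obs, ], ...)
  })
  names(fits) <- observers
  tab <- data.frame(
    observer_id = observers,
    N = vapply(fits, function(f) f$params_hat$N, integer(1)),
    sigma = vapply(fits, function(f) f$params_hat$sigma, numeric(1)),
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    n_trials = vapply(fits, function(f) f$n_trials, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  if (!is.null(out)) {
    write_json_stable(lapply(fits, function(f) {
      list(N = f$params_hat$N, sigma = f$params_hat$sigma, nll = f$nll,
           n_trials = f$n_trials)
    }), out)
    write.csv(tab, sub("\\.json$", ".csv", out), row.names = FALSE)
  }
  attr(fits, "table") <- tab
  invisible(fits)
}

#' Run the parameter-recovery study, with file output
#'
#' @param cfg An [ffr_config()] list; the `recovery` and `seed` fields are
#'   used.
#' @param out_dir Optional output directory for `recovery_runs.csv`,
#'   `recovery_summary.json` and a config snapshot.
#' @param verbose Log progress to stderr.
#' @return Invisibly, the [parameter_recovery()] result.
#' @export
ffr_recover <- function(cfg = ffr_config(), out_dir = NULL, verbose = FALSE) {
  validate_config(cfg)
  rec <- parameter_recovery(
    n_runs = cfg$recovery$n_runs,
    trials_per_run = cfg$recovery$trials_per_run,
    N_range = cfg$recovery$N_range,
    sigma_range = cfg$recovery$sigma_range,
    seed = cfg$seed, verbose = verbose, wheel = config_wheel(cfg)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rec$runs, file.path(out_dir, "recovery_runs.csv"),
              row.names = FALSE)
    write_json_stable(
      list(n_runs = rec$n_runs, trials_per_run = rec$trials_per_run,
           r_N = rec$r_N, r_sigma = rec$r_sigma, r_cross = rec$r_cross),
      file.path(out_dir, "recovery_summary.json"))
    write_config(cfg, file.path(out_dir, "config.json"))
  }
  invisible(rec)
}
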