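# Fixed-precision numeric formatting (6 dp) so identical runs produce
# byte-identical CSV output.
fmt6 <- function(x) sprintf("%.6f", x)

write_csv_plain <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, eol = "\n")
}

#' Write and read session trace CSV
#'
#' The trace CSV carries one row per sample with columns `time_s`,
#' `left_prob`, `right_prob`, `active` (0/1) and, when raw IMU channels are
#' present, `l_ax`..`l_az`, `r_ax`..`r_az`. Times and probabilities are
#' written with six decimal places. `read_trace_csv()` infers the sampling
#' rate from the median time step and validates uniformity (relative
#' tolerance 1e-6), probability ranges and required columns, reporting the
#' offending row on failure. Segments travel in a separate CSV (see
#' [write_segments_csv()]).
#'
#' @param session a [fog_session()].
#' @param path file path.
#' @return `read_trace_csv()` returns a [fog_session()] (without segments
#'   unless supplied); `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(session, path) {
  stopifnot(inherits(session, "fog_session"))
  df <- data.frame(
    time_s = fmt6(trace_times(session$left)),
    left_prob = fmt6(session$left$values),
    right_prob = fmt6(session$right$values),
    active = as.integer(session$active_mask)
  )
  if (!is.null(session$raw_imu)) {
    for (ft in c("left", "right")) {
      m <- session$raw_imu[[ft]]
      pre <- if (ft == "left") "l_a" else "r_a"
      for (j in 1:3) df[[paste0(pre, c("x", "y", "z")[j])]] <- fmt6(m[, j])
    }
  }
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param segments optional [fog_segments()] to attach to the session.
#' @export
read_trace_csv <- function(path, segments = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "left_prob", "right_prob", "active")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("trace CSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) < 2L) stop("trace CSV needs at least 2 rows", call. = FALSE)
  steps <- diff(df$time_s)
  med <- stats::median(steps)
  if (med <= 0) stop("trace CSV times must be strictly increasing", call. = FALSE)
  bad <- which(abs(steps - med) > 1e-6 * med)
  if (length(bad)) {
    stop(sprintf("non-uniform time base in trace CSV at line %d (data row %d)",
                 bad[1] + 2L, bad[1] + 1L), call. = FALSE)
  }
  for (col in c("left_prob", "right_prob")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad)) {
      stop(sprintf("probability out of [0, 1] in column %s at line %d (data row %d)",
                   col, bad[1] + 1L, bad[1]), call. = FALSE)
    }
  }
  rate <- 1 / med
  t0 <- df$time_s[1]
  raw <- NULL
  raw_cols <- c("l_ax", "l_ay", "l_az", "r_ax", "r_ay", "r_az")
  if (all(raw_cols %in% names(df))) {
    raw <- list(left = as.matrix(df[c("l_ax", "l_ay", "l_az")]),
                right = as.matrix(df[c("r_ax", "r_ay", "r_az")]))
    dimnames(raw$left) <- NULL; dimnames(raw$right) <- NULL
  }
  fog_session(
    probability_trace(df$left_prob, rate, start_time = t0, foot = "left"),
    probability_trace(df$right_prob, rate, start_time = t0, foot = "right"),
    active_mask = df$active != 0, segments = segments, raw_imu = raw
  )
}

#' Write and read interval CSV
#'
#' Interval CSVs carry half-open `[start_s, end_s)` rows with `label`,
#' `task` and `source` columns. Touching intervals (`end == next start`)
#' are legal; overlapping ones are rejected.
#'
#' @param intervals a [fog_intervals()].
#' @param path file path.
#' @return `read_intervals_csv()` returns a [fog_intervals()];
#'   `write_intervals_csv()` returns `path` invisibly.
#' @export
write_intervals_csv <- function(intervals, path) {
  stopifnot(inherits(intervals, "fog_intervals"))
  df <- data.frame(
    start_s = fmt6(intervals$start), end_s = fmt6(intervals$end),
    label = intervals$label, task = ifelse(is.na(intervals$task), "",
                                           intervals$task),
    source = rep(attr(intervals, "source"), length.out = nrow(intervals))
  )
  if (nrow(intervals) == 0L) {
    df <- df[0, c("start_s", "end_s", "label", "task", "source"), drop = FALSE]
  }
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(start_s = "numeric", end_s = "numeric"))
  need <- c("start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("interval CSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  src <- if ("source" %in% names(df) && nrow(df) > 0L) df$source[1] else "video"
  if (!src %in% c("video", "algorithm")) src <- "video"
  bad <- which(df$start_s >= df$end_s)
  if (length(bad)) {
    stop(sprintf("interval start >= end at line %d (data row %d)",
                 bad[1] + 1L, bad[1]), call. = FALSE)
  }
  if (nrow(df) == 0L) return(fog_intervals(source = src))
  fog_intervals(df$start_s, df$end_s,
                label = if ("label" %in% names(df)) df$label else NULL,
                task = if ("task" %in% names(df)) df$task else NULL,
                source = src)
}

#' Write and read task-segment CSV
#'
#' @param segments a [fog_segments()].
#' @param path file path.
#' @return `read_segments_csv()` returns a [fog_segments()];
#'   `write_segments_csv()` returns `path` invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  stopifnot(inherits(segments, "fog_segments"))
  df <- data.frame(task = segments$task, start_s = fmt6(segments$start),
                   end_s = fmt6(segments$end), category = segments$category,
                   dual_task = as.integer(segments$dual_task),
                   is_sedentary = as.integer(segments$is_sedentary))
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("segments CSV %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  fog_segments(df$task, df$start_s, df$end_s,
               category = if ("category" %in% names(df)) df$category else NULL,
               dual_task = if ("dual_task" %in% names(df))
                 df$dual_task != 0 else NULL,
               is_sedentary = if ("is_sedentary" %in% names(df))
                 df$is_sedentary != 0 else FALSE)
}

# Tiny FNV-1a hash of a deparsed object, for the run log.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline run configuration
#'
#' Exactly one input source must be given: either a synthetic configuration
#' (a cohort is generated) or paths to a recorded session's trace, interval
#' and segment CSVs.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed controlling every random draw of the run.
#' @param synthetic optional [fog_synth_config()].
#' @param n_participants cohort size for synthetic runs.
#' @param trace_csv,intervals_csv,segments_csv input paths for recorded
#'   sessions.
#' @param prediction a [prediction_config()].
#' @param rates sampling rates (Hz) for the sampling study; the study runs
#'   only when raw IMU channels are available.
#' @param detector detector name in the registry (see
#'   [register_detector()]).
#' @param taps resampling kernel length.
#' @return an object of class `fog_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, synthetic = NULL,
                       n_participants = 13L, trace_csv = NULL,
                       intervals_csv = NULL, segments_csv = NULL,
                       prediction = prediction_config(),
                       rates = c(100, 60, 30), detector = "surrogate",
                       taps = 21L) {
  has_synth <- !is.null(synthetic)
  has_files <- !is.null(trace_csv)
  if (has_synth == has_files) {
    stop("exactly one of `synthetic` or `trace_csv` must be given",
         call. = FALSE)
  }
  if (has_files && is.null(intervals_csv)) {
    stop("`intervals_csv` (ground truth) is required with `trace_csv`",
         call. = FALSE)
  }
  if (has_synth) stopifnot(inherits(synthetic, "fog_synth_config"))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
         n_participants = as.integer(n_participants), trace_csv = trace_csv,
         intervals_csv = intervals_csv, segments_csv = segments_csv,
         prediction = prediction, rates = rates, detector = detector,
         taps = as.integer(taps)),
    class = "fog_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `out_dir`, `seed`, `n_participants`,
#' `rates`, `detector`, `taps`, `trace_csv`, `intervals_csv`,
#' `segments_csv`, plus nested `synthetic:` (fields of
#' [fog_synth_config()]) and `prediction:` (fields of
#' [prediction_config()]).
#'
#' @param path YAML file path.
#' @param out_dir overrides the file's `out_dir` when non-NULL.
#' @param seed overrides the file's `seed` when non-NULL.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  synth <- NULL
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$task_plan)) {
      sy$task_plan <- do.call(rbind, lapply(sy$task_plan, as.data.frame))
    }
    if (!is.null(sy$tremble_band)) sy$tremble_band <- unlist(sy$tremble_band)
    synth <- do.call(fog_synth_config, sy)
  }
  pred <- if (!is.null(y$prediction)) {
    if (!is.null(y$prediction$thresholds)) {
      y$prediction$thresholds <- unlist(y$prediction$thresholds)
    }
    do.call(prediction_config, y$prediction)
  } else prediction_config()
  args <- list(
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    seed = if (!is.null(seed)) seed else if (!is.null(y$seed)) y$seed else 1L,
    synthetic = synth, prediction = pred
  )
  for (k in c("n_participants", "trace_csv", "intervals_csv", "segments_csv",
              "detector", "taps")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$rates)) args$rates <- unlist(y$rates)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analyses end to end and writes a report bundle to
#' `config$out_dir`: detected events (`events.csv`), the prediction
#' threshold sweep (`prediction_sweep.csv`), task potency
#' (`task_potency.csv`), the sampling-rate study
#' (`sampling_accuracy.csv`, `sampling_wtsf.csv`, and `stats.json` with
#' the ANOVA and Tukey tables) and a `run_log.txt` recording package
#' version, seed and configuration hash. All numeric output uses fixed
#' six-decimal formatting, so identical configuration + seed yields
#' byte-identical files. The sampling study (and its stats) is emitted
#' only when raw IMU channels are available and, for the ANOVA, when at
#' least two rates are requested.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the output `paths` and the in-memory
#'   result objects (`cohort`, `events`, `sweep`, `potency`, `study`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fog_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop("output directory is not writable", call. = FALSE)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic, config$n_participants,
                      seed = config$seed)
    } else {
      segs <- if (!is.null(config$segments_csv)) {
        read_segments_csv(config$segments_csv)
      } else NULL
      list(list(session = read_trace_csv(config$trace_csv, segments = segs),
                annotations = read_intervals_csv(config$intervals_csv)))
    }
  })

  paths <- list()
  ev_rows <- list()
  events <- stage("events", lapply(seq_along(cohort), function(p) {
    ses <- cohort[[p]]$session
    ev <- detect_events(combine_feet(ses$left, ses$right), 0.7, 2.0)
    if (nrow(ev)) {
      ev_rows[[p]] <<- data.frame(participant = p, start_s = fmt6(ev$start),
                                  end_s = fmt6(ev$end), source = "algorithm")
    }
    ev
  }))
  ev_df <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(participant = integer(0), start_s = character(0),
               end_s = character(0), source = character(0))
  paths$events <- file.path(config$out_dir, "events.csv")
  write_csv_plain(ev_df, paths$events)

  sweep <- stage("prediction", {
    parts <- lapply(seq_along(cohort), function(p) {
      list(session = cohort[[p]]$session, events = events[[p]])
    })
    threshold_sweep(parts, config$prediction)
  })
  paths$sweep <- file.path(config$out_dir, "prediction_sweep.csv")
  sw <- sweep
  for (cl in c("threshold", "true_rate_mean", "true_rate_sd",
               "false_rate_mean", "false_rate_sd")) {
    sw[[cl]] <- ifelse(is.na(sw[[cl]]), "", fmt6(sw[[cl]]))
  }
  write_csv_plain(as.data.frame(sw), paths$sweep)

  potency <- stage("potency", {
    task_potency(lapply(cohort, `[[`, "annotations"),
                 lapply(cohort, function(x) x$session$segments))
  })
  paths$potency <- file.path(config$out_dir, "task_potency.csv")
  po <- as.data.frame(potency)
  po$pct_of_sample <- fmt6(po$pct_of_sample)
  po$total_fog_duration_s <- fmt6(po$total_fog_duration_s)
  write_csv_plain(po, paths$potency)

  study <- NULL
  has_raw <- !is.null(cohort[[1]]$session$raw_imu)
  if (has_raw) {
    study <- stage("sampling-study", {
      sampling_study(lapply(cohort, `[[`, "session"),
                     lapply(cohort, `[[`, "annotations"),
                     detector = get_detector(config$detector),
                     rates = config$rates, taps = config$taps)
    })
    paths$sampling_accuracy <- file.path(config$out_dir,
                                         "sampling_accuracy.csv")
    sa <- study$results
    sa$accuracy_pct <- fmt6(sa$accuracy_pct)
    sa$wtsf_pct <- NULL
    write_csv_plain(sa, paths$sampling_accuracy)
    paths$sampling_wtsf <- file.path(config$out_dir, "sampling_wtsf.csv")
    sw2 <- study$results
    sw2$wtsf_pct <- fmt6(sw2$wtsf_pct)
    sw2$accuracy_pct <- NULL
    write_csv_plain(sw2, paths$sampling_wtsf)
    paths$stats <- file.path(config$out_dir, "stats.json")
    stats_obj <- list(
      anova = if (!is.null(study$anova)) {
        a <- study$anova
        list(F = a$F, df_between = a$df_between, df_within = a$df_within,
             p = a$p, alpha = a$alpha)
      } else NULL,
      tukey = if (!is.null(study$tukey)) as.data.frame(study$tukey) else NULL,
      summary = study$summary
    )
    jsonlite::write_json(stats_obj, paths$stats, auto_unbox = TRUE,
                         digits = 10, null = "null", pretty = TRUE)
  }

  paths$log <- file.path(config$out_dir, "run_log.txt")
  log_cfg <- config
  log_cfg$out_dir <- NULL    # hash the analysis settings, not the destination
  writeLines(c(
    sprintf("fogr version: %s", as.character(utils::packageVersion("fogr"))),
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s", config_hash(log_cfg)),
    sprintf("participants: %d", length(cohort)),
    sprintf("sampling study: %s", if (has_raw) "yes" else "no")
  ), paths$log)

  invisible(list(paths = paths, cohort = cohort, events = events,
                 sweep = sweep, potency = potency, study = study))
}
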