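#' Configuration for the pre-onset prediction rule
#'
#' The prediction rule declares an upcoming FOG event predicted when the
#' probability trace rises monotonically above a prediction threshold inside
#' the pre-onset window, with at least `lead_min_s` of lead before the event
#' onset (the first 0.7-crossing). Seven thresholds centred on 0.35 -- half
#' the 0.7 event threshold -- are swept by default.
#'
#' @param thresholds strictly increasing prediction thresholds in (0, 0.7).
#' @param window_s pre-onset window length in seconds.
#' @param lead_min_s minimum lead time (s) between a qualifying crossing and
#'   the event onset; set to 0 to count any pre-onset rise.
#' @param min_run_s minimum duration (s) of the non-decreasing run that must
#'   precede a counted crossing.
#' @param fp_horizon_s a crossing is a false alarm when no event onset
#'   follows within this horizon (s).
#' @param refractory_s minimum spacing (s) between counted crossings of the
#'   same threshold.
#' @return an object of class `fog_prediction_config`.
#' @export
prediction_config <- function(thresholds = c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5),
                              window_s = 3.0, lead_min_s = 1.0,
                              min_run_s = 0.25, fp_horizon_s = 3.0,
                              refractory_s = 1.0) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  if (any(thresholds <= 0) || any(thresholds >= 0.7)) {
    stop("`thresholds` must lie in (0, 0.7)", call. = FALSE)
  }
  if (lead_min_s < 0 || lead_min_s >= window_s) {
    stop("`lead_min_s` must satisfy 0 <= lead_min_s < window_s", call. = FALSE)
  }
  if (min_run_s < 0) stop("`min_run_s` must be >= 0", call. = FALSE)
  if (fp_horizon_s <= 0) stop("`fp_horizon_s` must be > 0", call. = FALSE)
  if (refractory_s < 0) stop("`refractory_s` must be >= 0", call. = FALSE)
  structure(
    list(thresholds = thresholds, window_s = window_s,
         lead_min_s = lead_min_s, min_run_s = min_run_s,
         fp_horizon_s = fp_horizon_s, refractory_s = refractory_s),
    class = "fog_prediction_config"
  )
}

#' Extract the pre-onset window of a trace
#'
#' Returns the samples in `[onset - window_s, onset)`, truncated at the
#' trace start -- the few seconds leading up to a freeze in which a warning
#' could still be delivered.
#'
#' @param trace a [probability_trace()].
#' @param onset event onset time in seconds.
#' @param window_s window length in seconds.
#' @return a `fog_trace` containing the window samples.
#' @export
extract_pre_onset_window <- function(trace, onset, window_s = 3.0) {
  stopifnot(inherits(trace, "fog_trace"))
  if (onset < trace$start_time - 1e-9) {
    stop("`onset` lies before the trace start", call. = FALSE)
  }
  if (onset > trace_end_time(trace) + 1e-9) {
    stop("`onset` lies after the trace end", call. = FALSE)
  }
  t <- trace_times(trace)
  keep <- t >= onset - window_s - 1e-12 & t < onset - 1e-12
  if (!any(keep)) {
    stop("pre-onset window contains no samples", call. = FALSE)
  }
  probability_trace(trace$values[keep], trace$sampling_rate,
                    start_time = t[which(keep)[1]], foot = trace$foot)
}

#' Find monotonic threshold crossings
#'
#' A crossing is the first sample strictly above `threshold` that is
#' preceded by a non-decreasing run of duration at least `min_run_s`
#' starting at or below the threshold. After a counted crossing the trace
#' must return to or below the threshold, and `refractory_s` must elapse,
#' before another crossing of the same threshold is counted.
#'
#' @param trace a [probability_trace()].
#' @param threshold prediction threshold in (0, 1).
#' @param config a [prediction_config()].
#' @return data.frame with columns `time` (s, the crossing sample's time),
#'   `threshold` and `run_length_s`.
#' @export
find_monotone_crossings <- function(trace, threshold,
                                    config = prediction_config()) {
  stopifnot(inherits(trace, "fog_trace"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  v <- trace$values
  n <- length(v)
  empty <- data.frame(time = numeric(0), threshold = numeric(0),
                      run_length_s = numeric(0))
  if (n < 2L) return(empty)
  fs <- trace$sampling_rate
  # run_start[i]: first index of the maximal non-decreasing run ending at i
  idx <- seq_len(n)
  new_run <- c(TRUE, diff(v) < 0)
  run_start <- cummax(ifelse(new_run, idx, 0L))
  cand <- which(v > threshold & c(TRUE, v[-n] <= threshold))
  cand <- cand[cand > 1L]                      # must rise from <= threshold
  if (!length(cand)) return(empty)
  rl <- (cand - run_start[cand]) / fs
  ok <- rl >= config$min_run_s - 1e-12 & v[run_start[cand]] <= threshold
  cand <- cand[ok]; rl <- rl[ok]
  if (!length(cand)) return(empty)
  times <- trace$start_time + (cand - 1L) / fs
  # refractory: keep a crossing only refractory_s after the last kept one
  keep <- logical(length(cand))
  last_t <- -Inf
  for (i in seq_along(cand)) {
    if (times[i] >= last_t + config$refractory_s - 1e-12) {
      keep[i] <- TRUE
      last_t <- times[i]
    }
  }
  data.frame(time = times[keep], threshold = threshold,
             run_length_s = rl[keep])
}

#' Evaluate pre-onset predictions against detected events
#'
#' An event is counted as predicted when some monotonic crossing of the
#' prediction threshold lies in `[onset - window_s, onset - lead_min_s]`,
#' where the onset is the event's first sample time from [detect_events()].
#' A crossing is a false alarm when no event onset follows within
#' `fp_horizon_s`. Crossings occurring inside an ongoing event are
#' discarded: prediction is only meaningful before onset.
#'
#' @param trace the combined probability trace the events were detected on.
#' @param events a [fog_intervals()] of detected FOG events (pre-merged,
#'   disjoint).
#' @param threshold prediction threshold in (0, 0.7).
#' @param config a [prediction_config()].
#' @return an object of class `fog_prediction_counts`: counts `n_events`,
#'   `n_predicted`, `n_crossings`, `n_false_crossings` and rates
#'   `true_rate` = n_predicted/n_events, `false_rate` =
#'   n_false_crossings/n_crossings (`NA` when the denominator is zero).
#' @export
evaluate_predictions <- function(trace, events, threshold,
                                 config = prediction_config()) {
  stopifnot(inherits(trace, "fog_trace"))
  if (nrow(events) > 1L) {
    o <- order(events$start)
    if (any(events$start[o][-1] < events$end[o][-nrow(events)] - 1e-9)) {
      stop("events must be disjoint (pre-merged)", call. = FALSE)
    }
  }
  cr <- find_monotone_crossings(trace, threshold, config)
  if (nrow(cr) > 0L && nrow(events) > 0L) {
    inside <- points_in_intervals(cr$time, events)
    cr <- cr[!inside, , drop = FALSE]
  }
  onsets <- if (nrow(events)) sort(events$start) else numeric(0)
  n_events <- length(onsets)
  predicted <- vapply(onsets, function(on) {
    any(cr$time >= on - config$window_s - 1e-9 &
          cr$time <= on - config$lead_min_s + 1e-9)
  }, logical(1))
  false_cr <- vapply(cr$time, function(tc) {
    !any(onsets > tc + 1e-9 & onsets <= tc + config$fp_horizon_s + 1e-9)
  }, logical(1))
  n_predicted <- sum(predicted)
  n_crossings <- nrow(cr)
  n_false <- sum(false_cr)
  structure(
    list(threshold = threshold, n_events = n_events,
         n_predicted = n_predicted, n_crossings = n_crossings,
         n_false_crossings = n_false,
         true_rate = if (n_events > 0) n_predicted / n_events else NA_real_,
         false_rate = if (n_crossings > 0) n_false / n_crossings else NA_real_),
    class = "fog_prediction_counts"
  )
}

#' @export
print.fog_prediction_counts <- function(x, ...) {
  cat(sprintf(
    "<fog_prediction_counts> threshold %.2f: %d/%d events predicted (true rate %s), %d/%d crossings false (false rate %s)\n",
    x$threshold, x$n_predicted, x$n_events,
    ifelse(is.na(x$true_rate), "NA", sprintf("%.2f", x$true_rate)),
    x$n_false_crossings, x$n_crossings,
    ifelse(is.na(x$false_rate), "NA", sprintf("%.2f", x$false_rate))))
  invisible(x)
}

# Normalise one cohort element to list(trace=, events=).
sweep_element <- function(el, threshold_event = 0.7, merge_gap = 2.0) {
  if (inherits(el, "fog_session")) {
    tr <- combine_feet(el$left, el$right)
    return(list(trace = tr, events = detect_events(tr, threshold_event, merge_gap)))
  }
  if (is.list(el) && !is.null(el$session) && inherits(el$session, "fog_session")) {
    tr <- combine_feet(el$session$left, el$session$right)
    ev <- if (!is.null(el$events)) el$events else
      detect_events(tr, threshold_event, merge_gap)
    return(list(trace = tr, events = ev))
  }
  if (is.list(el) && !is.null(el$trace)) {
    ev <- if (!is.null(el$events)) el$events else
      detect_events(el$trace, threshold_event, merge_gap)
    return(list(trace = el$trace, events = ev))
  }
  stop("cohort elements must be fog_session objects or lists with $session/$trace",
       call. = FALSE)
}

#' Sweep prediction thresholds across a cohort
#'
#' Evaluates the prediction rule at every configured threshold for every
#' participant and summarises the per-participant true and false prediction
#' rates as mean (SD) per threshold. Participants with zero detected events
#' are excluded from the true-rate average; participants with zero counted
#' crossings are excluded from the false-rate average.
#'
#' @param cohort a list of participants; each element is a `fog_session`, or
#'   a list with `$session` (and optionally `$events`), or a list with
#'   `$trace` (and optionally `$events`).
#' @param config a [prediction_config()].
#' @param event_threshold,merge_gap passed to [detect_events()] when a
#'   cohort element does not already carry events.
#' @return a `data.frame` of class `fog_sweep` with one row per threshold:
#'   `threshold`, `true_rate_mean`, `true_rate_sd`, `false_rate_mean`,
#'   `false_rate_sd`, `n_true_participants`, `n_false_participants`.
#' @export
threshold_sweep <- function(cohort, config = prediction_config(),
                            event_threshold = 0.7, merge_gap = 2.0) {
  if (!is.list(cohort) || length(cohort) < 1L) {
    stop("`cohort` must be a non-empty list of participants", call. = FALSE)
  }
  parts <- lapply(cohort, sweep_element, event_threshold, merge_gap)
  rows <- lapply(config$thresholds, function(th) {
    res <- lapply(parts, function(p) {
      evaluate_predictions(p$trace, p$events, th, config)
    })
    tr <- vapply(res, `[[`, numeric(1), "true_rate")
    fr <- vapply(res, `[[`, numeric(1), "false_rate")
    tr <- tr[!is.na(tr)]; fr <- fr[!is.na(fr)]
    data.frame(
      threshold = th,
      true_rate_mean = if (length(tr)) mean(tr) else NA_real_,
      true_rate_sd = if (length(tr) > 1L) stats::sd(tr) else
        if (length(tr) == 1L) 0 else NA_real_,
      false_rate_mean = if (length(fr)) mean(fr) else NA_real_,
      false_rate_sd = if (length(fr) > 1L) stats::sd(fr) else
        if (length(fr) == 1L) 0 else NA_real_,
      n_true_participants = length(tr),
      n_false_participants = length(fr)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fog_sweep", "data.frame")
  out
}

#' @export
print.fog_sweep <- function(x, ...) {
  cat("<fog_sweep> prediction-rate sweep; mean (SD) across participants\n")
  df <- data.frame(
    threshold = sprintf("%.2f", x$threshold),
    true_rate = sprintf("%.2f (%.2f)", x$true_rate_mean, x$true_rate_sd),
    false_rate = sprintf("%.2f (%.2f)", x$false_rate_mean, x$false_rate_sd)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
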