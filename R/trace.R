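#' Construct a FOG probability trace
#'
#' A `fog_trace` holds a uniformly sampled sequence of freezing-of-gait
#' probabilities in \[0, 1\] for one foot (or the combined either-foot
#' signal), together with its sampling rate and start time. Sample `i`
#' (0-based) covers the half-open interval
#' `[start_time + i/rate, start_time + (i+1)/rate)`.
#'
#' @param values numeric vector of probabilities in \[0, 1\], length >= 1.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds.
#' @param foot one of `"left"`, `"right"`, `"combined"`.
#' @return an object of class `fog_trace`.
#' @export
#' @examples
#' tr <- probability_trace(c(0.1, 0.8, 0.2), sampling_rate = 10)
#' trace_times(tr)
probability_trace <- function(values, sampling_rate, start_time = 0,
                              foot = c("combined", "left", "right")) {
  foot <- match.arg(foot)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("`values` must contain at least one sample", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stop("`values` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time), foot = foot),
    class = "fog_trace"
  )
}

#' Sample times of a trace
#'
#' @param trace a [probability_trace()].
#' @return numeric vector of sample start times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "fog_trace"))
  trace$start_time + (seq_along(trace$values) - 1) / trace$sampling_rate
}

# End of the time span covered by a trace (seconds).
trace_end_time <- function(trace) {
  trace$start_time + length(trace$values) / trace$sampling_rate
}

#' @export
print.fog_trace <- function(x, ...) {
  cat(sprintf(
    "<fog_trace> foot=%s, %d samples @ %g Hz, t = [%.3f, %.3f) s, range [%.3f, %.3f]\n",
    x$foot, length(x$values), x$sampling_rate, x$start_time,
    trace_end_time(x), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
plot.fog_trace <- function(x, threshold = 0.7, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = "P(FOG)", ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Combine left and right foot traces
#'
#' An FOG event is declared when either foot's probability is above the
#' event threshold, so the combined signal is the pointwise maximum of the
#' two feet.
#'
#' @param left,right `fog_trace` objects with identical length, sampling
#'   rate and start time.
#' @return a `fog_trace` with `foot = "combined"`.
#' @export
combine_feet <- function(left, right) {
  stopifnot(inherits(left, "fog_trace"), inherits(right, "fog_trace"))
  if (length(left$values) != length(right$values)) {
    stop("left and right traces differ in length", call. = FALSE)
  }
  if (abs(left$sampling_rate - right$sampling_rate) >
      1e-9 * max(left$sampling_rate, right$sampling_rate)) {
    stop("left and right traces differ in sampling rate", call. = FALSE)
  }
  if (abs(left$start_time - right$start_time) > 1e-9) {
    stop("left and right traces differ in start time", call. = FALSE)
  }
  probability_trace(pmax(left$values, right$values),
                    sampling_rate = left$sampling_rate,
                    start_time = left$start_time, foot = "combined")
}

#' Task segmentation of a session
#'
#' Ordered, non-overlapping half-open task intervals covering (part of) a
#' session. Task categories follow the in-lab protocol: the walking
#' provocation tasks (Hallway, GOT = Go Outside and Turn, 360-degree turn,
#' each single- or dual-task) are `clinic_fog`; simulated instrumental
#' activities of daily living (vacuuming, dishwasher, sitting, community
#' navigation) are `iadl`.
#'
#' @param task character vector of task names (non-empty strings).
#' @param start,end segment boundaries in seconds, half-open `[start, end)`.
#' @param category optional; inferred from the task name when `NULL`.
#' @param dual_task optional logical; inferred from a `DT` suffix when `NULL`.
#' @param is_sedentary logical; sedentary segments carry no active time.
#' @return a `data.frame` of class `fog_segments`.
#' @export
fog_segments <- function(task, start, end, category = NULL,
                         dual_task = NULL, is_sedentary = FALSE) {
  task <- as.character(task)
  if (any(!nzchar(task))) stop("task names must be non-empty", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) {
    stop("segment start must be < end", call. = FALSE)
  }
  if (is.null(category)) category <- task_category(task)
  if (is.null(dual_task)) dual_task <- grepl("[- ]?DT$", task)
  df <- data.frame(task = task, start = start, end = end,
                   category = category, dual_task = dual_task,
                   is_sedentary = rep_len(is_sedentary, length(task)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start[-1] < df$end[-nrow(df)] - 1e-9)) {
    stop("segments must be non-overlapping", call. = FALSE)
  }
  class(df) <- c("fog_segments", "data.frame")
  df
}

clinic_fog_tasks <- function() {
  c("Hallway", "Hallway-DT", "GOT", "GOT-DT", "360", "360-DT")
}

task_category <- function(task) {
  ifelse(sub("[- ]?DT$", "", task) %in% sub("[- ]?DT$", "", clinic_fog_tasks()),
         "clinic_fog", "iadl")
}

#' Assemble a session recording
#'
#' Bundles the paired per-foot probability traces with the hip-sensor
#' derived active-time mask, the ordered task segmentation and (optionally)
#' surrogate raw tri-axial foot accelerations. All per-sample series share
#' one length and one sampling rate.
#'
#' @param left,right per-foot [probability_trace()] objects.
#' @param active_mask logical vector, one element per sample; `TRUE` marks
#'   active (walking) time. Samples inside sedentary segments must be
#'   inactive.
#' @param segments optional [fog_segments()].
#' @param raw_imu optional list with elements `left` and `right`, each an
#'   n-by-3 numeric matrix of accelerations on the same sample grid.
#' @return an object of class `fog_session`.
#' @export
fog_session <- function(left, right, active_mask, segments = NULL,
                        raw_imu = NULL) {
  stopifnot(inherits(left, "fog_trace"), inherits(right, "fog_trace"))
  n <- length(left$values)
  if (length(right$values) != n) {
    stop("left and right traces differ in length", call. = FALSE)
  }
  if (abs(left$sampling_rate - right$sampling_rate) > 1e-9 * left$sampling_rate) {
    stop("left and right traces differ in sampling rate", call. = FALSE)
  }
  active_mask <- as.logical(active_mask)
  if (length(active_mask) != n || anyNA(active_mask)) {
    stop("`active_mask` must be a logical vector matching the trace length",
         call. = FALSE)
  }
  if (!is.null(segments)) {
    stopifnot(inherits(segments, "fog_segments"))
    sed <- segments[segments$is_sedentary, , drop = FALSE]
    if (nrow(sed) > 0L) {
      centers <- left$start_time + (seq_len(n) - 0.5) / left$sampling_rate
      in_sed <- rep(FALSE, n)
      for (i in seq_len(nrow(sed))) {
        in_sed <- in_sed | (centers >= sed$start[i] & centers < sed$end[i])
      }
      if (any(active_mask & in_sed)) {
        stop("active_mask must be FALSE throughout sedentary segments",
             call. = FALSE)
      }
    }
  }
  if (!is.null(raw_imu)) {
    if (!is.list(raw_imu) || !all(c("left", "right") %in% names(raw_imu))) {
      stop("`raw_imu` must be a list with elements `left` and `right`",
           call. = FALSE)
    }
    for (ft in c("left", "right")) {
      m <- raw_imu[[ft]]
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L) {
        stop(sprintf("raw_imu$%s must be an n-by-3 matrix", ft), call. = FALSE)
      }
    }
  }
  structure(
    list(left = left, right = right, active_mask = active_mask,
         segments = segments, raw_imu = raw_imu,
         sampling_rate = left$sampling_rate, start_time = left$start_time),
    class = "fog_session"
  )
}

#' @export
print.fog_session <- function(x, ...) {
  n <- length(x$left$values)
  cat(sprintf(
    "<fog_session> %d samples @ %g Hz (%.1f s), %.1f s active, %s segments, raw IMU: %s\n",
    n, x$sampling_rate, n / x$sampling_rate,
    sum(x$active_mask) / x$sampling_rate,
    if (is.null(x$segments)) "no" else nrow(x$segments),
    if (is.null(x$raw_imu)) "no" else "yes"
  ))
  invisible(x)
}

#' Half-open event/annotation intervals
#'
#' A sorted, pairwise-disjoint set of half-open `[start, end)` time
#' intervals, either algorithm-detected FOG events or video-style
#' ground-truth annotations.
#'
#' @param start,end numeric vectors of interval boundaries in seconds.
#' @param label optional per-interval labels (default `"FOG"`).
#' @param task optional task name each interval falls in.
#' @param source `"algorithm"` or `"video"`.
#' @param rater_id optional rater identifier (annotations).
#' @return a `data.frame` of class `fog_intervals` with attributes
#'   `source` and `rater_id`.
#' @export
fog_intervals <- function(start = numeric(), end = numeric(), label = NULL,
                          task = NULL, source = c("video", "algorithm"),
                          rater_id = NULL) {
  source <- match.arg(source)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("`start` and `end` must have equal length", call. = FALSE)
  }
  if (any(start >= end)) stop("interval start must be < end", call. = FALSE)
  if (is.null(label)) label <- rep_len("FOG", length(start))
  if (is.null(task)) task <- rep_len(NA_character_, length(start))
  df <- data.frame(start = start, end = end,
                   label = as.character(rep_len(label, length(start))),
                   task = as.character(rep_len(task, length(start))),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start[-1] < df$end[-nrow(df)] - 1e-9)) {
    stop("intervals must be pairwise disjoint", call. = FALSE)
  }
  attr(df, "source") <- source
  attr(df, "rater_id") <- rater_id
  class(df) <- c("fog_intervals", "data.frame")
  df
}

#' @export
print.fog_intervals <- function(x, ...) {
  cat(sprintf("<fog_intervals> %d interval(s), source=%s, total %.2f s\n",
              nrow(x), attr(x, "source"), sum(x$end - x$start)))
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

# Logical membership of time points in a sorted disjoint interval set.
points_in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, intervals$start)
  idx >= 1L & t < intervals$end[pmax(idx, 1L)]
}
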