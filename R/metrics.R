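#' Detection accuracy from confusion durations
#'
#' Accuracy is the ratio of time classified true positive plus time
#' classified true negative to the total analyzed time, expressed as a
#' percentage.
#'
#' @param conf a [fog_confusion()].
#' @return accuracy in percent (0--100).
#' @export
#' @examples
#' accuracy(fog_confusion(10, 5, 80, 5, 100))  # 90
accuracy <- function(conf) {
  stopifnot(inherits(conf, "fog_confusion"))
  if (conf$analyzed_s <= 0) {
    stop("accuracy undefined: analyzed time is zero", call. = FALSE)
  }
  100 * (conf$tp_s + conf$tn_s) / conf$analyzed_s
}

#' Percent of active walking time spent freezing (%WTSF)
#'
#' Total freezing time within active samples divided by total active time,
#' times 100. Freeze coverage is evaluated by sample-center containment on
#' the session grid, so event time falling in sedentary (inactive) samples
#' does not count.
#'
#' @param events a [fog_intervals()] of FOG events.
#' @param active_mask logical vector, one element per grid sample.
#' @param sampling_rate grid rate in Hz.
#' @param start_time time of the first grid sample (s).
#' @return %WTSF in percent (0--100).
#' @export
wtsf <- function(events, active_mask, sampling_rate, start_time = 0) {
  active_mask <- as.logical(active_mask)
  n_active <- sum(active_mask)
  if (n_active == 0L) {
    stop("%WTSF undefined: active time is zero", call. = FALSE)
  }
  centers <- start_time + (seq_along(active_mask) - 0.5) / sampling_rate
  in_ev <- points_in_intervals(centers, events)
  pct <- 100 * sum(in_ev & active_mask) / n_active
  min(max(pct, 0), 100)
}

#' Per-task and per-category accuracy and %WTSF
#'
#' Restricts the time-based confusion to each task segment's active samples
#' and reports accuracy and %WTSF per task, per category (clinic FOG tasks
#' vs. simulated IADLs) and overall. Category and overall figures pool
#' confusion *times* across segments rather than averaging task
#' percentages, consistent with accuracy being a time ratio. Sedentary
#' tasks contribute no analyzed time and are reported as absent; active
#' samples outside every segment are excluded with a warning.
#'
#' @param session a [fog_session()] carrying the active mask and segments
#'   (or pass `segments` explicitly).
#' @param algo_events algorithm events, a [fog_intervals()].
#' @param truth ground-truth annotations, a [fog_intervals()].
#' @param segments a [fog_segments()]; defaults to `session$segments`.
#' @return an object of class `fog_accuracy_report`: `overall_pct`,
#'   `overall_wtsf_pct`, `per_task` (data.frame), `per_category`
#'   (data.frame) and the pooled `confusion`.
#' @export
per_task_metrics <- function(session, algo_events, truth,
                             segments = session$segments) {
  stopifnot(inherits(session, "fog_session"))
  if (is.null(segments)) {
    stop("`segments` are required for per-task metrics", call. = FALSE)
  }
  fs <- session$sampling_rate
  n <- length(session$active_mask)
  centers <- session$start_time + (seq_len(n) - 0.5) / fs
  in_algo <- points_in_intervals(centers, algo_events)
  in_truth <- points_in_intervals(centers, truth)
  act <- session$active_mask

  seg_of <- rep(NA_integer_, n)
  for (i in seq_len(nrow(segments))) {
    hit <- centers >= segments$start[i] & centers < segments$end[i]
    seg_of[hit] <- i
  }
  orphan <- act & is.na(seg_of)
  if (any(orphan)) {
    warning(sprintf("%d active sample(s) outside all segments excluded from per-task metrics",
                    sum(orphan)), call. = FALSE)
  }

  task_rows <- lapply(seq_len(nrow(segments)), function(i) {
    sel <- act & !is.na(seg_of) & seg_of == i
    n_act <- sum(sel)
    data.frame(
      task = segments$task[i], category = segments$category[i],
      analyzed_s = n_act / fs,
      tp_s = sum(sel & in_algo & in_truth) / fs,
      fp_s = sum(sel & in_algo & !in_truth) / fs,
      tn_s = sum(sel & !in_algo & !in_truth) / fs,
      fn_s = sum(sel & !in_algo & in_truth) / fs,
      freeze_s = sum(sel & in_algo) / fs,
      stringsAsFactors = FALSE
    )
  })
  per_seg <- do.call(rbind, task_rows)
  # pool multiple segments of the same task name
  agg <- stats::aggregate(per_seg[c("analyzed_s", "tp_s", "fp_s", "tn_s",
                                    "fn_s", "freeze_s")],
                          by = list(task = per_seg$task,
                                    category = per_seg$category), FUN = sum)
  present <- agg$analyzed_s > 0
  per_task <- agg[present, , drop = FALSE]
  per_task$accuracy_pct <- 100 * (per_task$tp_s + per_task$tn_s) / per_task$analyzed_s
  per_task$wtsf_pct <- 100 * per_task$freeze_s / per_task$analyzed_s
  per_task <- per_task[order(match(per_task$task, segments$task)),
                       c("task", "category", "analyzed_s", "accuracy_pct",
                         "wtsf_pct")]
  rownames(per_task) <- NULL

  cat_agg <- stats::aggregate(agg[c("analyzed_s", "tp_s", "tn_s", "freeze_s")],
                              by = list(category = agg$category), FUN = sum)
  cat_agg <- cat_agg[cat_agg$analyzed_s > 0, , drop = FALSE]
  per_category <- data.frame(
    category = cat_agg$category,
    analyzed_s = cat_agg$analyzed_s,
    accuracy_pct = 100 * (cat_agg$tp_s + cat_agg$tn_s) / cat_agg$analyzed_s,
    wtsf_pct = 100 * cat_agg$freeze_s / cat_agg$analyzed_s,
    stringsAsFactors = FALSE
  )
  rownames(per_category) <- NULL

  scored <- act & !is.na(seg_of)
  analyzed <- sum(scored) / fs
  conf <- fog_confusion(
    tp_s = sum(scored & in_algo & in_truth) / fs,
    fp_s = sum(scored & in_algo & !in_truth) / fs,
    tn_s = sum(scored & !in_algo & !in_truth) / fs,
    fn_s = sum(scored & !in_algo & in_truth) / fs,
    analyzed_s = analyzed, sampling_rate = fs
  )
  structure(
    list(overall_pct = if (analyzed > 0) accuracy(conf) else NA_real_,
         overall_wtsf_pct = if (analyzed > 0)
           100 * sum(scored & in_algo) / sum(scored) else NA_real_,
         per_task = per_task, per_category = per_category, confusion = conf),
    class = "fog_accuracy_report"
  )
}

#' @export
print.fog_accuracy_report <- function(x, ...) {
  cat(sprintf("<fog_accuracy_report> overall accuracy %.1f%%, overall %%WTSF %.1f%%\n",
              x$overall_pct, x$overall_wtsf_pct))
  df <- x$per_task
  df$analyzed_s <- sprintf("%.1f", df$analyzed_s)
  df$accuracy_pct <- sprintf("%.1f", df$accuracy_pct)
  df$wtsf_pct <- sprintf("%.1f", df$wtsf_pct)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Task potency for eliciting FOG across a cohort
#'
#' For each task, counts the participants with at least one ground-truth
#' FOG annotation overlapping that task's segments, and sums the annotated
#' FOG duration falling within the task across participants. Potency is
#' assessed on the video-style ground truth, not on algorithm events.
#'
#' @param annotations list (one element per participant) of
#'   [fog_intervals()] ground-truth annotation sets.
#' @param segments list (one element per participant) of [fog_segments()].
#' @return a `data.frame` of class `fog_potency` with columns `task`,
#'   `n_participants_with_fog`, `pct_of_sample`, `total_fog_duration_s`.
#' @export
task_potency <- function(annotations, segments) {
  if (!is.list(annotations) || !is.list(segments) ||
      length(annotations) != length(segments) || length(annotations) < 1L) {
    stop("`annotations` and `segments` must be equal-length non-empty lists",
         call. = FALSE)
  }
  n_part <- length(annotations)
  tasks <- unique(unlist(lapply(segments, function(s) s$task)))
  rows <- lapply(tasks, function(tk) {
    with_fog <- 0L
    total_dur <- 0
    for (p in seq_len(n_part)) {
      seg <- segments[[p]]
      seg <- seg[seg$task == tk, , drop = FALSE]
      ann <- annotations[[p]]
      if (nrow(seg) == 0L || nrow(ann) == 0L) next
      dur <- 0
      for (i in seq_len(nrow(seg))) {
        ov <- pmin(ann$end, seg$end[i]) - pmax(ann$start, seg$start[i])
        dur <- dur + sum(ov[ov > 0])
      }
      if (dur > 0) with_fog <- with_fog + 1L
      total_dur <- total_dur + dur
    }
    data.frame(task = tk, n_participants_with_fog = with_fog,
               pct_of_sample = 100 * with_fog / n_part,
               total_fog_duration_s = total_dur, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fog_potency", "data.frame")
  attr(out, "n_participants") <- n_part
  out
}

#' @export
print.fog_potency <- function(x, ...) {
  cat(sprintf("<fog_potency> task potency across %d participant(s)\n",
              attr(x, "n_participants")))
  df <- data.frame(
    task = x$task,
    participants_with_fog = sprintf("%d (%.0f%%)", x$n_participants_with_fog,
                                    x$pct_of_sample),
    total_fog_s = sprintf("%.1f", x$total_fog_duration_s)
  )
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
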