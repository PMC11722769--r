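#' Detect FOG events in a probability trace
#'
#' An FOG event is any maximal run of samples whose probability is strictly
#' above `threshold` (0.7 by convention). Events separated by a gap strictly
#' shorter than `merge_gap` (2 s by convention) are merged into one episode;
#' merging is applied left-to-right until a fixed point, so every remaining
#' inter-event gap is at least `merge_gap`. Intervals are half-open on the
#' sample grid: a supra-threshold run of samples `i..j` (0-based) becomes
#' `[t0 + i/fs, t0 + (j+1)/fs)`.
#'
#' @param trace a [probability_trace()]; usually the combined either-foot
#'   signal from [combine_feet()].
#' @param threshold event threshold in (0, 1); samples exactly at the
#'   threshold are non-freeze.
#' @param merge_gap minimum separation (s) for two events to stay distinct.
#' @return a [fog_intervals()] with `source = "algorithm"`.
#' @export
#' @examples
#' tr <- probability_trace(c(0, 0.8, 0.9, 0, 0, 0.8, 0), 10)
#' detect_events(tr, merge_gap = 0.1)
detect_events <- function(trace, threshold = 0.7, merge_gap = 2.0) {
  stopifnot(inherits(trace, "fog_trace"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  if (merge_gap < 0) stop("`merge_gap` must be >= 0", call. = FALSE)
  above <- trace$values > threshold
  if (!any(above)) {
    return(fog_intervals(source = "algorithm"))
  }
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  fs <- trace$sampling_rate
  s <- trace$start_time + (starts_i[keep] - 1L) / fs
  e <- trace$start_time + ends_i[keep] / fs
  # left-to-right transitive merge of gaps strictly below merge_gap
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] - me < merge_gap - 1e-12) {
        me <- e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  fog_intervals(out_s, out_e, source = "algorithm")
}

#' Confusion durations container
#'
#' @param tp_s,fp_s,tn_s,fn_s durations in seconds.
#' @param analyzed_s total analyzed (active) duration in seconds.
#' @param sampling_rate the sample grid rate used for classification.
#' @return an object of class `fog_confusion`.
#' @export
fog_confusion <- function(tp_s, fp_s, tn_s, fn_s, analyzed_s,
                          sampling_rate = NA_real_) {
  vals <- c(tp_s, fp_s, tn_s, fn_s, analyzed_s)
  if (any(vals < 0)) stop("confusion durations must be >= 0", call. = FALSE)
  if (abs((tp_s + fp_s + tn_s + fn_s) - analyzed_s) >
      1 / max(sampling_rate, 1, na.rm = TRUE) + 1e-9) {
    stop("tp + fp + tn + fn must equal the analyzed time", call. = FALSE)
  }
  structure(list(tp_s = tp_s, fp_s = fp_s, tn_s = tn_s, fn_s = fn_s,
                 analyzed_s = analyzed_s, sampling_rate = sampling_rate),
            class = "fog_confusion")
}

#' @export
print.fog_confusion <- function(x, ...) {
  cat(sprintf(
    "<fog_confusion> analyzed %.2f s: TP %.2f, FP %.2f, TN %.2f, FN %.2f (s)\n",
    x$analyzed_s, x$tp_s, x$fp_s, x$tn_s, x$fn_s))
  invisible(x)
}

#' Score algorithm events against ground truth as time-based confusion
#'
#' Classifies every active sample of the session grid: true positive where
#' both the algorithm events and the ground-truth annotations cover the
#' sample, true negative where neither does, false positive for
#' algorithm-only and false negative for truth-only coverage. Sedentary
#' (inactive) samples are excluded from the analysis entirely. Intervals are
#' mapped onto the grid by sample-center containment, and durations are
#' sample counts divided by the sampling rate, so
#' `tp + fp + tn + fn == analyzed` holds exactly.
#'
#' @param algo algorithm events, a [fog_intervals()] (or data.frame with
#'   `start`/`end`).
#' @param truth ground-truth annotations, a [fog_intervals()].
#' @param active_mask logical vector, one element per grid sample.
#' @param sampling_rate grid rate in Hz.
#' @param start_time time of the first grid sample (s).
#' @return a [fog_confusion()].
#' @export
classify_time <- function(algo, truth, active_mask, sampling_rate,
                          start_time = 0) {
  active_mask <- as.logical(active_mask)
  n <- length(active_mask)
  if (n < 1L) stop("`active_mask` must be non-empty", call. = FALSE)
  span_end <- start_time + n / sampling_rate
  for (iv in list(algo = algo, truth = truth)) {
    if (nrow(iv) > 0L &&
        (min(iv$start) < start_time - 1e-9 || max(iv$end) > span_end + 1e-9)) {
      stop("interval outside the session time span", call. = FALSE)
    }
  }
  centers <- start_time + (seq_len(n) - 0.5) / sampling_rate
  in_algo <- points_in_intervals(centers, algo)
  in_truth <- points_in_intervals(centers, truth)
  act <- active_mask
  fs <- sampling_rate
  fog_confusion(
    tp_s = sum(act & in_algo & in_truth) / fs,
    fp_s = sum(act & in_algo & !in_truth) / fs,
    tn_s = sum(act & !in_algo & !in_truth) / fs,
    fn_s = sum(act & !in_algo & in_truth) / fs,
    analyzed_s = sum(act) / fs,
    sampling_rate = fs
  )
}
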