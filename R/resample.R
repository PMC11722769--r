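#' Windowed-sinc resampling of a uniform series
#'
#' Sampling-rate conversion by bandlimited interpolation with a 21-point
#' sinc kernel under a Hanning window, the standard anti-aliased "resample"
#' operation. The cutoff sits at half the lower of the two rates, so
#' down-sampling low-pass filters at the destination Nyquist while
#' up-sampling interpolates at the source Nyquist. The input is
#' reflect-padded so the output covers the input's full duration
#' (`round(n * dst/src)` samples); per-output kernel normalisation makes DC
#' signals pass through exactly.
#'
#' @param values numeric vector sampled uniformly at `src_rate`.
#' @param src_rate,dst_rate source and destination rates in Hz.
#' @param taps kernel length in points (odd, >= 3).
#' @return numeric vector at `dst_rate`.
#' @export
resample_signal <- function(values, src_rate, dst_rate, taps = 21L) {
  values <- as.numeric(values)
  n <- length(values)
  if (src_rate <= 0 || dst_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  taps <- as.integer(taps)
  if (taps < 3L || taps %% 2L == 0L) {
    stop("`taps` must be odd and >= 3", call. = FALSE)
  }
  if (n < taps) {
    stop(sprintf("input length %d is shorter than the %d-point filter", n, taps),
         call. = FALSE)
  }
  M <- (taps - 1L) %/% 2L
  n_out <- max(1L, as.integer(round(n * dst_rate / src_rate)))
  # output sample k sits at t = k / dst_rate; c = position in input-sample units
  cpos <- (seq_len(n_out) - 1L) * src_rate / dst_rate
  fc <- min(src_rate, dst_rate) / 2
  # reflect padding (no edge duplication)
  left_pad <- values[seq(M + 1L, 2L)]
  right_pad <- values[seq(n - 1L, n - M)]
  xp <- c(left_pad, values, right_pad)
  base <- floor(cpos)
  num <- numeric(n_out)
  den <- numeric(n_out)
  for (d in (-M):M) {
    k <- base + d                     # 0-based input index
    tau <- (cpos - k) / src_rate      # seconds from tap to output point
    u <- cpos - k                     # input-sample units, |u| <= M + 1
    w <- 0.5 + 0.5 * cos(pi * u / (M + 1))
    arg <- 2 * fc * tau
    s <- ifelse(abs(arg) < 1e-12, 1, sin(pi * arg) / (pi * arg))
    h <- w * s
    num <- num + h * xp[k + M + 1L]
    den <- den + h
  }
  num / den
}

#' Resample a session to a new rate
#'
#' Applies [resample_signal()] coherently to every per-sample series of the
#' session: both probability traces (clipped back to \[0, 1\] after
#' filtering) and, when present, all raw IMU channels. The active-time mask
#' is mapped by nearest source sample -- masks and annotations are never
#' low-pass filtered -- and the task segmentation, which lives in seconds,
#' is unchanged.
#'
#' @param session a [fog_session()].
#' @param dst_rate destination rate in Hz.
#' @param taps kernel length for [resample_signal()].
#' @return a [fog_session()] at `dst_rate`.
#' @export
resample_session <- function(session, dst_rate, taps = 21L) {
  stopifnot(inherits(session, "fog_session"))
  src <- session$sampling_rate
  if (abs(dst_rate - src) < 1e-9) return(session)
  rs_prob <- function(tr, foot) {
    v <- resample_signal(tr$values, src, dst_rate, taps)
    probability_trace(pmin(pmax(v, 0), 1), dst_rate,
                      start_time = tr$start_time, foot = foot)
  }
  left <- rs_prob(session$left, "left")
  right <- rs_prob(session$right, "right")
  n_out <- length(left$values)
  # nearest-source-sample mask mapping
  src_idx <- pmin(pmax(round((seq_len(n_out) - 1L) * src / dst_rate) + 1L, 1L),
                  length(session$active_mask))
  mask <- session$active_mask[src_idx]
  raw <- NULL
  if (!is.null(session$raw_imu)) {
    raw <- lapply(session$raw_imu, function(m) {
      out <- vapply(seq_len(ncol(m)), function(j) {
        resample_signal(m[, j], src, dst_rate, taps)
      }, numeric(n_out))
      matrix(out, ncol = ncol(m))
    })
  }
  fog_session(left, right, active_mask = mask, segments = session$segments,
              raw_imu = raw)
}

#' End-to-end sampling-rate degradation study
#'
#' For each requested rate, resamples every participant's session, runs the
#' detector to obtain per-foot probability traces, extracts FOG events from
#' the combined trace (threshold 0.7, 2 s merge), and scores them against
#' the fixed ground-truth annotations as overall accuracy and %WTSF over
#' active time. With two or more rates, overall accuracies are compared
#' across rates by [one_way_anova()] with [tukey_hsd()] post hoc.
#'
#' @param cohort list of [fog_session()] objects (one per participant),
#'   carrying whatever channels the detector needs.
#' @param annotations list of ground-truth [fog_intervals()], parallel to
#'   `cohort`.
#' @param detector function mapping a session to
#'   `list(left = , right = )` probability traces at the session's rate;
#'   see [surrogate_detector()] and [passthrough_detector()].
#' @param rates numeric vector of rates (Hz) to evaluate.
#' @param event_threshold,merge_gap event extraction parameters.
#' @param taps resampling kernel length.
#' @param per_task logical; also compute per-task accuracy reports (needs
#'   segments on every session).
#' @param alpha significance level for the ANOVA/Tukey comparison.
#' @return an object of class `fog_sampling_study`: `results` (long
#'   data.frame: participant, rate, accuracy_pct, wtsf_pct), `summary`
#'   (per-rate mean/sd), `per_task` (per-rate mean accuracy by task, or
#'   NULL), `anova` (`fog_anova` or NULL), `tukey` (`fog_tukey` or NULL).
#' @export
sampling_study <- function(cohort, annotations, detector = surrogate_detector(),
                           rates = c(100, 60, 30), event_threshold = 0.7,
                           merge_gap = 2.0, taps = 21L, per_task = TRUE,
                           alpha = 0.05) {
  if (!is.list(cohort) || length(cohort) < 1L) {
    stop("`cohort` must be a non-empty list of sessions", call. = FALSE)
  }
  if (length(annotations) != length(cohort)) {
    stop("`annotations` must parallel `cohort`", call. = FALSE)
  }
  rows <- list()
  task_rows <- list()
  for (r in rates) {
    for (p in seq_along(cohort)) {
      ses_r <- resample_session(cohort[[p]], r, taps = taps)
      traces <- tryCatch(detector(ses_r), error = function(e) {
        stop(sprintf("detector failed on participant %d at %g Hz: %s",
                     p, r, conditionMessage(e)), call. = FALSE)
      })
      comb <- combine_feet(traces$left, traces$right)
      events <- detect_events(comb, event_threshold, merge_gap)
      conf <- classify_time(events, annotations[[p]], ses_r$active_mask,
                            ses_r$sampling_rate, ses_r$start_time)
      acc <- accuracy(conf)
      w <- wtsf(events, ses_r$active_mask, ses_r$sampling_rate,
                ses_r$start_time)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, rate = r, accuracy_pct = acc, wtsf_pct = w)
      if (per_task && !is.null(ses_r$segments)) {
        rep_ <- per_task_metrics(ses_r, events, annotations[[p]])
        tdf <- rep_$per_task
        tdf$participant <- p
        tdf$rate <- r
        task_rows[[length(task_rows) + 1L]] <- tdf
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(rates, function(r) {
    a <- results$accuracy_pct[results$rate == r]
    w <- results$wtsf_pct[results$rate == r]
    data.frame(rate = r, accuracy_mean = mean(a),
               accuracy_sd = if (length(a) > 1) stats::sd(a) else 0,
               wtsf_mean = mean(w),
               wtsf_sd = if (length(w) > 1) stats::sd(w) else 0)
  }))
  per_task_tab <- NULL
  if (length(task_rows)) {
    tall <- do.call(rbind, task_rows)
    per_task_tab <- stats::aggregate(
      cbind(accuracy_pct, wtsf_pct) ~ task + category + rate, data = tall,
      FUN = mean)
    per_task_tab <- per_task_tab[order(per_task_tab$rate,
                                       per_task_tab$task), ]
    rownames(per_task_tab) <- NULL
  }
  an <- NULL; tk <- NULL
  if (length(rates) >= 2L && length(cohort) >= 2L) {
    groups <- lapply(rates, function(r) results$accuracy_pct[results$rate == r])
    names(groups) <- paste0(rates, "Hz")
    an <- one_way_anova(groups, alpha = alpha)
    tk <- tukey_hsd(groups, alpha = alpha)
  }
  structure(
    list(rates = rates, results = results, summary = summ,
         per_task = per_task_tab, anova = an, tukey = tk),
    class = "fog_sampling_study"
  )
}

#' @export
print.fog_sampling_study <- function(x, ...) {
  cat(sprintf("<fog_sampling_study> %d participant(s) x rates {%s} Hz\n",
              length(unique(x$results$participant)),
              paste(x$rates, collapse = ", ")))
  df <- data.frame(
    rate = x$summary$rate,
    accuracy = sprintf("%.1f%% (%.1f)", x$summary$accuracy_mean,
                       x$summary$accuracy_sd),
    wtsf = sprintf("%.1f%% (%.1f)", x$summary$wtsf_mean, x$summary$wtsf_sd)
  )
  print.data.frame(df, row.names = FALSE)
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

#' @export
summary.fog_sampling_study <- function(object, ...) {
  print(object)
  if (!is.null(object$tukey)) print(object$tukey)
  if (!is.null(object$per_task)) {
    cat("per-task mean accuracy:\n")
    print.data.frame(object$per_task, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.fog_sampling_study <- function(x, ...) {
  graphics::boxplot(accuracy_pct ~ rate, data = x$results,
                    xlab = "sampling rate (Hz)", ylab = "accuracy (%)", ...)
  invisible(x)
}
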