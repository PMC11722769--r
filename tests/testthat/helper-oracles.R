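# Independent brute-force oracles and fixture builders. These deliberately
# use naive O(n*m) scans so they share no code path with the implementation.

# mark samples above threshold, scan runs, then repeatedly merge gaps
oracle_detect_events <- function(values, fs, threshold = 0.7,
                                 merge_gap = 2.0, t0 = 0) {
  above <- values > threshold
  ivs <- list()
  i <- 1L
  n <- length(values)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      ivs[[length(ivs) + 1L]] <- c(t0 + (i - 1) / fs, t0 + j / fs)
      i <- j + 1L
    } else i <- i + 1L
  }
  repeat {
    merged <- FALSE
    if (length(ivs) >= 2L) {
      for (k in seq_len(length(ivs) - 1L)) {
        if (ivs[[k + 1L]][1] - ivs[[k]][2] < merge_gap) {
          ivs[[k]] <- c(ivs[[k]][1], ivs[[k + 1L]][2])
          ivs[[k + 1L]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  if (!length(ivs)) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = vapply(ivs, `[`, numeric(1), 1),
             end = vapply(ivs, `[`, numeric(1), 2))
}

# per-sample loop classification
oracle_classify <- function(algo, truth, mask, fs, t0 = 0) {
  n <- length(mask)
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  in_set <- function(tc, iv) {
    if (nrow(iv) == 0L) return(FALSE)
    any(tc >= iv$start & tc < iv$end)
  }
  for (i in seq_len(n)) {
    if (!mask[i]) next
    tc <- t0 + (i - 0.5) / fs
    a <- in_set(tc, algo)
    b <- in_set(tc, truth)
    key <- if (a && b) "tp" else if (a) "fp" else if (b) "fn" else "tn"
    counts[key] <- counts[key] + 1L
  }
  counts / fs
}

# exhaustive scan over all crossing candidates and their runs
oracle_crossings <- function(values, fs, threshold, min_run_s, refractory_s,
                             t0 = 0) {
  n <- length(values)
  out <- numeric(0)
  last <- -Inf
  for (i in 2:n) {
    if (!(values[i] > threshold && values[i - 1L] <= threshold)) next
    j <- i
    while (j > 1L && values[j - 1L] <= values[j]) j <- j - 1L
    if ((i - j) / fs < min_run_s) next
    if (values[j] > threshold) next
    tc <- t0 + (i - 1) / fs
    if (tc < last + refractory_s) next
    out <- c(out, tc)
    last <- tc
  }
  out
}

# analytic amplitude response of the resampling kernel at frequency f
oracle_kernel_response <- function(f, src_rate, dst_rate, taps = 21) {
  M <- (taps - 1) / 2
  m <- -M:M
  fc <- min(src_rate, dst_rate) / 2
  w <- 0.5 + 0.5 * cos(pi * m / (M + 1))
  arg <- 2 * fc * m / src_rate
  s <- ifelse(abs(arg) < 1e-12, 1, sin(pi * arg) / (pi * arg))
  h <- w * s
  h <- h / sum(h)
  Mod(sum(h * exp(-2i * pi * f * m / src_rate)))
}

# steady-state amplitude of a resampled sinusoid, edges trimmed
measured_amplitude <- function(y, dst_rate, trim_s = 1) {
  k <- round(trim_s * dst_rate)
  max(abs(y[(k + 1):(length(y) - k)]))
}

# a single-ramp trace: baseline then linear ramp p0 -> p1 over ramp_s
make_ramp_trace <- function(fs = 100, ramp_start = 5, ramp_s = 3,
                            p0 = 0.05, p1 = 0.95, total_s = 20,
                            hold_s = 3, decay_s = 1) {
  t <- (0:(total_s * fs - 1)) / fs
  v <- rep(p0, length(t))
  i <- t >= ramp_start & t < ramp_start + ramp_s
  v[i] <- p0 + (p1 - p0) * (t[i] - ramp_start) / ramp_s
  i <- t >= ramp_start + ramp_s & t < ramp_start + ramp_s + hold_s
  v[i] <- p1
  i <- t >= ramp_start + ramp_s + hold_s &
    t < ramp_start + ramp_s + hold_s + decay_s
  v[i] <- p1 - (p1 - p0) * (t[i] - ramp_start - ramp_s - hold_s) / decay_s
  probability_trace(v, fs)
}

# random piecewise trace hovering around a threshold; exercises runs/gaps
random_trace <- function(fs = 20, dur_s = 30, p_high = 0.3) {
  n <- fs * dur_s
  state <- stats::runif(n) < p_high
  v <- ifelse(state, stats::runif(n, 0.65, 1), stats::runif(n, 0, 0.72))
  probability_trace(pmin(pmax(v, 0), 1), fs)
}

random_intervals <- function(span, k, source = "video") {
  if (k == 0L) return(fog_intervals(source = source))
  pts <- sort(stats::runif(2 * k, 0, span))
  s <- pts[seq(1, 2 * k, 2)]
  e <- pts[seq(2, 2 * k, 2)]
  ok <- e - s > 1e-3
  if (!any(ok)) return(fog_intervals(source = source))
  fog_intervals(s[ok], e[ok], source = source)
}
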