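# Seeded evaluation helper: runs code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647
  as.integer(max(1, s))
}

#' Default in-lab task plan
#'
#' The ten-task session layout used throughout: three clinic FOG
#' provocation tasks (Hallway, GOT, 360-degree turn), each in single- and
#' dual-task form, plus four simulated IADLs (vacuuming, dishwasher,
#' sitting, community navigation). Sitting is sedentary and serves to
#' verify that no FOG is flagged off the feet.
#'
#' @return data.frame with columns `task`, `duration_s`, `is_sedentary`.
#' @export
default_task_plan <- function() {
  data.frame(
    task = c("Hallway", "Hallway-DT", "GOT", "GOT-DT", "360", "360-DT",
             "Vacuuming", "Dishwasher", "Sitting", "Community"),
    duration_s = c(60, 60, 60, 60, 45, 45, 90, 90, 90, 120),
    is_sedentary = c(rep(FALSE, 8), TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic session configuration
#'
#' Parameters of the seeded session generator that stands in for wearable
#' recordings. Each planted freeze is a piecewise-linear probability
#' excursion: a monotonic pre-onset ramp from `ramp_start_prob` to
#' `ramp_peak_prob` over `ramp_duration` seconds (crossing the 0.7 event
#' threshold on the way up -- that crossing is the ground-truth onset), a
#' plateau of `freeze_hold` seconds at the peak, then a linear decay over
#' `decay_duration` seconds (the ground-truth offset is the 0.7
#' down-crossing). False rises follow the same shape but peak at
#' `false_rise_peak` below 0.7, so they trigger the prediction rule without
#' ever becoming events. Baseline probability is Gaussian noise clipped to
#' \[0, 1\]. Each freeze lands on one randomly chosen foot; the other foot
#' stays at baseline, exercising the either-foot event rule.
#'
#' @param seed integer RNG seed; the generator is a pure function of the
#'   configuration including this seed.
#' @param sampling_rate trace rate in Hz.
#' @param task_plan data.frame with `task`, `duration_s`, `is_sedentary`.
#' @param freezes_per_task expected freeze count per active task (Poisson
#'   mean).
#' @param freeze_counts exact-count override: a single integer applied to
#'   every active task, or a named vector/list by task name. `NULL` keeps
#'   Poisson counts.
#' @param ramp_duration pre-onset ramp length (s).
#' @param ramp_start_prob,ramp_peak_prob ramp endpoints; the peak must
#'   exceed 0.7 so planted freezes are detectable.
#' @param freeze_hold plateau duration at the peak (s).
#' @param decay_duration fall time from peak back to baseline (s).
#' @param false_rise_rate expected sub-0.7 rises per active minute.
#' @param false_rise_peak false-rise peak probability, below 0.7.
#' @param baseline_mean,baseline_sd baseline probability noise parameters.
#' @param annotation_jitter_sd SD (s) of rater-style onset/offset jitter
#'   applied to the returned annotations; 0 keeps the planted truth exact.
#' @param emit_raw_imu also synthesize surrogate tri-axial foot
#'   accelerations (see [synthesize_raw_imu()]).
#' @param locomotion_freq stride frequency of the walking sinusoid (Hz).
#' @param tremble_band range (Hz) the trembling fundamental is drawn from
#'   during freezes.
#' @param locomotion_amp,tremble_amp,freeze_sway_amp,noise_sd,sedentary_scale
#'   raw-signal amplitude parameters (arbitrary acceleration units).
#' @param tremble_harmonics relative amplitudes of the 2nd and 3rd
#'   harmonics of the trembling oscillation (trembling is non-sinusoidal).
#' @return an object of class `fog_synth_config`.
#' @export
fog_synth_config <- function(seed = 1L, sampling_rate = 100,
                             task_plan = default_task_plan(),
                             freezes_per_task = 1.5, freeze_counts = NULL,
                             ramp_duration = 3.0, ramp_start_prob = 0.05,
                             ramp_peak_prob = 0.95, freeze_hold = 3.0,
                             decay_duration = 1.0, false_rise_rate = 2,
                             false_rise_peak = 0.6, baseline_mean = 0.05,
                             baseline_sd = 0.01, annotation_jitter_sd = 0,
                             emit_raw_imu = FALSE, locomotion_freq = 2,
                             tremble_band = c(3, 8), locomotion_amp = 1.0,
                             tremble_amp = 1.4,
                             tremble_harmonics = c(0.8, 0.55),
                             freeze_sway_amp = 1.0, noise_sd = 0.1,
                             sedentary_scale = 0.05) {
  fail <- function(field, msg) {
    stop(sprintf("invalid synthetic config: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (sampling_rate <= 0) fail("sampling_rate", "must be > 0")
  if (!is.data.frame(task_plan) ||
      !all(c("task", "duration_s", "is_sedentary") %in% names(task_plan))) {
    fail("task_plan", "must have columns task, duration_s, is_sedentary")
  }
  if (any(task_plan$duration_s <= 0)) fail("task_plan", "durations must be > 0")
  if (ramp_start_prob < 0 || ramp_start_prob >= ramp_peak_prob ||
      ramp_peak_prob > 1) {
    fail("ramp_start_prob/ramp_peak_prob",
         "must satisfy 0 <= start < peak <= 1")
  }
  if (ramp_peak_prob <= 0.7) fail("ramp_peak_prob", "must exceed 0.7")
  if (ramp_duration <= 0) fail("ramp_duration", "must be > 0")
  if (freeze_hold <= 0) fail("freeze_hold", "must be > 0")
  if (decay_duration <= 0) fail("decay_duration", "must be > 0")
  if (false_rise_peak >= 0.7) fail("false_rise_peak", "must be below 0.7")
  if (false_rise_peak <= ramp_start_prob) {
    fail("false_rise_peak", "must exceed ramp_start_prob")
  }
  if (false_rise_rate < 0) fail("false_rise_rate", "must be >= 0")
  if (freezes_per_task < 0) fail("freezes_per_task", "must be >= 0")
  if (baseline_sd < 0) fail("baseline_sd", "must be >= 0")
  if (baseline_mean < 0 || baseline_mean > 1) {
    fail("baseline_mean", "must be in [0, 1]")
  }
  if (annotation_jitter_sd < 0) fail("annotation_jitter_sd", "must be >= 0")
  if (length(tremble_band) != 2L || any(tremble_band <= 0) ||
      tremble_band[1] >= tremble_band[2]) {
    fail("tremble_band", "must be an increasing positive (lo, hi) pair")
  }
  structure(
    list(seed = as.integer(seed), sampling_rate = sampling_rate,
         task_plan = task_plan, freezes_per_task = freezes_per_task,
         freeze_counts = freeze_counts, ramp_duration = ramp_duration,
         ramp_start_prob = ramp_start_prob, ramp_peak_prob = ramp_peak_prob,
         freeze_hold = freeze_hold, decay_duration = decay_duration,
         false_rise_rate = false_rise_rate, false_rise_peak = false_rise_peak,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         annotation_jitter_sd = annotation_jitter_sd,
         emit_raw_imu = isTRUE(emit_raw_imu),
         locomotion_freq = locomotion_freq, tremble_band = tremble_band,
         locomotion_amp = locomotion_amp, tremble_amp = tremble_amp,
         tremble_harmonics = tremble_harmonics,
         freeze_sway_amp = freeze_sway_amp, noise_sd = noise_sd,
         sedentary_scale = sedentary_scale),
    class = "fog_synth_config"
  )
}

# Piecewise-linear excursion profile evaluated on sample times.
# r0: ramp start time. Returns the profile (0 outside the excursion).
excursion_profile <- function(t, r0, p0, p1, ramp, hold, decay) {
  peak_t <- r0 + ramp
  hold_end <- peak_t + hold
  fall_end <- hold_end + decay
  out <- numeric(length(t))
  i <- t >= r0 & t < peak_t
  out[i] <- p0 + (p1 - p0) * (t[i] - r0) / ramp
  i <- t >= peak_t & t < hold_end
  out[i] <- p1
  i <- t >= hold_end & t < fall_end
  out[i] <- p1 - (p1 - p0) * (t[i] - hold_end) / decay
  out
}

# Freeze counts per active task row, honouring exact-count overrides.
planned_counts <- function(config, active_rows) {
  k <- integer(length(active_rows))
  for (j in seq_along(active_rows)) {
    tk <- config$task_plan$task[active_rows[j]]
    fc <- config$freeze_counts
    if (!is.null(fc)) {
      k[j] <- if (!is.null(names(fc)) && tk %in% names(fc)) {
        as.integer(fc[[tk]])
      } else if (is.null(names(fc))) as.integer(fc[[1]]) else 0L
    } else {
      k[j] <- stats::rpois(1, config$freezes_per_task)
    }
  }
  k
}

#' Generate one synthetic session with ground truth
#'
#' Builds a full in-lab session at the configured sampling rate: per-foot
#' probability traces with baseline noise, planted freeze excursions and
#' sub-threshold false rises, the active-time mask (inactive throughout
#' sedentary tasks), the task segmentation, and the exact ground-truth
#' annotation set (the planted 0.7 up-/down-crossing times, optionally
#' jittered). Identical configurations produce bit-identical output.
#'
#' Events are spaced so that consecutive planted freezes never merge under
#' the 2 s rule, and false rises are kept clear of true onsets by more than
#' the default false-alarm horizon. If a task is too short for its planted
#' count, the count is reduced to what fits.
#'
#' @param config a [fog_synth_config()].
#' @return list with elements `session` ([fog_session()]) and
#'   `annotations` ([fog_intervals()], `source = "video"`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "fog_synth_config"))
  with_seed(config$seed, generate_session_impl(config))
}

generate_session_impl <- function(config) {
  fs <- config$sampling_rate
  plan <- config$task_plan
  ends <- cumsum(plan$duration_s)
  starts <- c(0, ends[-length(ends)])
  segments <- fog_segments(plan$task, starts, ends,
                           is_sedentary = plan$is_sedentary)
  total <- ends[length(ends)]
  n <- as.integer(round(total * fs))
  t <- (seq_len(n) - 1) / fs
  centers <- (seq_len(n) - 0.5) / fs

  mask <- rep(TRUE, n)
  sed <- segments[segments$is_sedentary, , drop = FALSE]
  for (i in seq_len(nrow(sed))) {
    mask[centers >= sed$start[i] & centers < sed$end[i]] <- FALSE
  }

  p0 <- config$ramp_start_prob
  p1 <- config$ramp_peak_prob
  ramp <- config$ramp_duration
  hold <- config$freeze_hold
  decay <- config$decay_duration
  onset_off <- ramp * (0.7 - p0) / (p1 - p0)
  offset_off <- ramp + hold + decay * (p1 - 0.7) / (p1 - p0)
  footprint <- ramp + hold + decay + 3.0   # >= 2 s merge gap + margin
  edge <- 0.5

  active_rows <- which(!plan$is_sedentary)
  k <- planned_counts(config, active_rows)
  ev_r0 <- numeric(0); ev_task <- character(0)
  for (j in seq_along(active_rows)) {
    i <- active_rows[j]
    dur <- plan$duration_s[i]
    kk <- k[j]
    while (kk > 0L && kk * footprint + 2 * edge > dur) kk <- kk - 1L
    if (kk == 0L) next
    slack <- dur - kk * footprint - 2 * edge
    offs <- sort(stats::runif(kk, 0, slack))
    r0 <- starts[i] + edge + offs + (seq_len(kk) - 1) * footprint
    ev_r0 <- c(ev_r0, r0)
    ev_task <- c(ev_task, rep(plan$task[i], kk))
  }
  ev_foot <- if (length(ev_r0)) sample(c("left", "right"), length(ev_r0),
                                       replace = TRUE) else character(0)

  # false rises: rejection-sampled into active time, clear of true events
  fr_dur <- ramp + decay
  n_fr <- stats::rpois(1, config$false_rise_rate * sum(mask) / fs / 60)
  excl_s <- ev_r0 - (fr_dur + 3.0 + 1.0)      # keep clear of onsets by > horizon
  excl_e <- ev_r0 + offset_off + 1.0
  fr_r0 <- numeric(0)
  fr_foot <- character(0)
  act_seg <- segments[!segments$is_sedentary, , drop = FALSE]
  if (n_fr > 0L && nrow(act_seg) > 0L) {
    w <- act_seg$end - act_seg$start
    for (i in seq_len(n_fr)) {
      for (try in 1:200) {
        si <- sample.int(nrow(act_seg), 1, prob = w)
        cand <- stats::runif(1, act_seg$start[si] + edge,
                             act_seg$end[si] - fr_dur - edge)
        clear_true <- !any(cand < excl_e & cand + fr_dur > excl_s)
        clear_fr <- !any(abs(cand - fr_r0) < fr_dur + 2.0)
        if (clear_true && clear_fr) {
          fr_r0 <- c(fr_r0, cand)
          fr_foot <- c(fr_foot, sample(c("left", "right"), 1))
          break
        }
      }
    }
  }

  traces <- list(
    left = pmin(pmax(stats::rnorm(n, config$baseline_mean,
                                  config$baseline_sd), 0), 1),
    right = pmin(pmax(stats::rnorm(n, config$baseline_mean,
                                   config$baseline_sd), 0), 1)
  )
  for (i in seq_along(ev_r0)) {
    prof <- excursion_profile(t, ev_r0[i], p0, p1, ramp, hold, decay)
    traces[[ev_foot[i]]] <- pmax(traces[[ev_foot[i]]], prof)
  }
  for (i in seq_along(fr_r0)) {
    prof <- excursion_profile(t, fr_r0[i], p0, config$false_rise_peak,
                              ramp, 0, decay)
    traces[[fr_foot[i]]] <- pmax(traces[[fr_foot[i]]], prof)
  }

  left <- probability_trace(traces$left, fs, foot = "left")
  right <- probability_trace(traces$right, fs, foot = "right")

  ann_s <- ev_r0 + onset_off
  ann_e <- ev_r0 + offset_off
  if (config$annotation_jitter_sd > 0 && length(ann_s)) {
    o <- order(ann_s)
    ann_s <- ann_s[o]; ann_e <- ann_e[o]
    js <- ann_s + stats::rnorm(length(ann_s), 0, config$annotation_jitter_sd)
    je <- ann_e + stats::rnorm(length(ann_e), 0, config$annotation_jitter_sd)
    # truncate so intervals never invert, overlap, or leave the session
    for (i in seq_along(js)) {
      lo <- if (i > 1) je[i - 1] + 1e-3 else 0
      hi <- if (i < length(js)) ann_s[i + 1] else total
      js[i] <- min(max(js[i], lo), ann_e[i] - 0.2)
      je[i] <- min(max(je[i], js[i] + 0.2), hi)
    }
    ann_s <- js; ann_e <- je
    ev_task <- ev_task[o]
  } else if (length(ann_s)) {
    o <- order(ann_s)
    ann_s <- ann_s[o]; ann_e <- ann_e[o]; ev_task <- ev_task[o]
  }
  annotations <- fog_intervals(ann_s, ann_e, task = ev_task,
                               source = "video", rater_id = "synthetic")

  session <- fog_session(left, right, active_mask = mask, segments = segments)
  if (config$emit_raw_imu) {
    session <- synth_raw_impl(session, config)
  }
  list(session = session, annotations = annotations)
}

#' Generate a cohort of independent synthetic sessions
#'
#' Derives one sub-seed per participant from `seed` and generates that many
#' independent sessions. Optionally plants freezes in only a subset of
#' participants (the remainder get zero freezes), mirroring cohorts in
#' which not every participant exhibits FOG in the lab.
#'
#' @param config a [fog_synth_config()]; its own `seed` is overridden per
#'   participant.
#' @param n_participants number of sessions (>= 1).
#' @param seed cohort-level seed.
#' @param n_with_fog optional; number of participants (chosen at random)
#'   whose sessions contain planted freezes. Others are generated with
#'   zero freezes.
#' @return list of `list(session =, annotations =)` elements.
#' @export
generate_cohort <- function(config, n_participants, seed = config$seed,
                            n_with_fog = NULL) {
  stopifnot(inherits(config, "fog_synth_config"))
  if (n_participants < 1L) {
    stop("`n_participants` must be >= 1", call. = FALSE)
  }
  if (!is.null(n_with_fog) &&
      (n_with_fog < 0L || n_with_fog > n_participants)) {
    stop("`n_with_fog` must be between 0 and n_participants", call. = FALSE)
  }
  plan <- with_seed(seed, {
    list(seeds = sample.int(2147483646L, n_participants),
         fog_ids = if (!is.null(n_with_fog))
           sample.int(n_participants, n_with_fog) else NULL)
  })
  lapply(seq_len(n_participants), function(i) {
    cfg <- config
    cfg$seed <- plan$seeds[i]
    if (!is.null(plan$fog_ids) && !(i %in% plan$fog_ids)) {
      cfg$freeze_counts <- 0L
    }
    generate_session(cfg)
  })
}

#' Add surrogate raw IMU channels to a session
#'
#' Synthesizes tri-axial foot accelerations consistent with the session's
#' probability traces: a stride-frequency locomotion sinusoid plus wideband
#' noise during active non-freeze time, a non-sinusoidal trembling burst
#' (fundamental drawn from `tremble_band`, plus 2nd and 3rd harmonics) with
#' a low-frequency sway component during each freeze, and near-silence
#' during sedentary time. Per-foot freeze intervals are recovered from the
#' session's own probability traces (0.7 threshold), so the bursts land
#' exactly on the planted freezes. Seeded and deterministic.
#'
#' @param session a [fog_session()].
#' @param config a [fog_synth_config()] with `emit_raw_imu = TRUE`.
#' @return the session with `raw_imu` channels attached.
#' @export
synthesize_raw_imu <- function(session, config) {
  stopifnot(inherits(session, "fog_session"),
            inherits(config, "fog_synth_config"))
  if (!config$emit_raw_imu) {
    stop("config does not request raw IMU (`emit_raw_imu` is FALSE)",
         call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 7919L), synth_raw_impl(session, config))
}

# Core raw-IMU builder; runs inside an established RNG state.
synth_raw_impl <- function(session, config) {
  fs <- session$sampling_rate
  n <- length(session$left$values)
  t <- trace_times(session$left)
  centers <- session$start_time + (seq_len(n) - 0.5) / fs
  h2 <- config$tremble_harmonics[1]
  h3 <- if (length(config$tremble_harmonics) > 1)
    config$tremble_harmonics[2] else 0
  raw <- list()
  for (ft in c("left", "right")) {
    m <- matrix(stats::rnorm(3L * n, 0, config$noise_sd), ncol = 3L)
    events <- detect_events(session[[ft]], 0.7, 2.0)
    in_freeze <- points_in_intervals(centers, events)
    walk <- session$active_mask & !in_freeze
    phase <- if (ft == "left") 0 else pi
    m[walk, 1] <- m[walk, 1] + config$locomotion_amp *
      sin(2 * pi * config$locomotion_freq * t[walk] + phase)
    m[walk, 2] <- m[walk, 2] + 0.4 * config$locomotion_amp *
      sin(4 * pi * config$locomotion_freq * t[walk] + phase)
    for (i in seq_len(nrow(events))) {
      sel <- centers >= events$start[i] & centers < events$end[i]
      if (!any(sel)) next
      f0 <- stats::runif(1, config$tremble_band[1], config$tremble_band[2])
      ph <- stats::runif(4, 0, 2 * pi)
      tt <- t[sel]
      burst <- config$tremble_amp *
        (sin(2 * pi * f0 * tt + ph[1]) +
           h2 * sin(2 * pi * 2 * f0 * tt + ph[2]) +
           h3 * sin(2 * pi * 3 * f0 * tt + ph[3]))
      sway <- config$freeze_sway_amp * sin(2 * pi * 1.5 * tt + ph[4])
      m[sel, 1] <- m[sel, 1] + burst + sway
      m[sel, 2] <- m[sel, 2] + 0.5 * burst
    }
    sedent <- !session$active_mask
    m[sedent, ] <- m[sedent, ] * config$sedentary_scale
    raw[[ft]] <- m
  }
  fog_session(session$left, session$right, active_mask = session$active_mask,
              segments = session$segments, raw_imu = raw)
}
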