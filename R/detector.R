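#' Surrogate detector specification
#'
#' Parameters of the spectral-ratio surrogate detector that maps raw foot
#' accelerations to a freeze probability. Per sliding window, the ratio of
#' freeze-band to (freeze + locomotion)-band power is squashed through a
#' logistic. The locomotion band (0.5--3 Hz) covers stride-frequency
#' content; the freeze band starts at 3 Hz, the classical trembling
#' fundamental range, and extends to 15 Hz so that the harmonics of
#' non-sinusoidal trembling are measured -- which is what makes the
#' detector degrade when down-sampling removes spectral content near the
#' 30 Hz Nyquist. The surrogate makes no claim of equivalence to any
#' specific published detector; it exists so end-to-end pipelines are
#' testable.
#'
#' @param name label for the registry.
#' @param window_s sliding-window length (s).
#' @param step_s hop between window centres (s).
#' @param freeze_band,locomotion_band frequency bands (Hz), non-overlapping.
#' @param logistic_midpoint,logistic_slope squashing parameters mapping the
#'   band-power ratio to \[0, 1\].
#' @param min_power windows whose combined band power falls below this
#'   floor are treated as non-movement (probability ~ 0).
#' @return an object of class `fog_detector_spec`.
#' @export
detector_spec <- function(name = "spectral-ratio", window_s = 2.0,
                          step_s = 0.1, freeze_band = c(3, 15),
                          locomotion_band = c(0.5, 3),
                          logistic_midpoint = 0.75, logistic_slope = 35,
                          min_power = 0.05) {
  if (window_s <= step_s) stop("`window_s` must exceed `step_s`", call. = FALSE)
  for (nm in c("freeze_band", "locomotion_band")) {
    b <- get(nm)
    if (length(b) != 2L || any(b <= 0) || b[1] >= b[2]) {
      stop(sprintf("`%s` must be an increasing positive (lo, hi) pair", nm),
           call. = FALSE)
    }
  }
  if (min(freeze_band[2], locomotion_band[2]) >
      max(freeze_band[1], locomotion_band[1])) {
    stop("freeze and locomotion bands must not overlap", call. = FALSE)
  }
  structure(
    list(name = name, window_s = window_s, step_s = step_s,
         freeze_band = freeze_band, locomotion_band = locomotion_band,
         logistic_midpoint = logistic_midpoint,
         logistic_slope = logistic_slope, min_power = min_power),
    class = "fog_detector_spec"
  )
}

# Periodogram band power of a (detrended) window, summed across columns.
band_powers <- function(seg, fs, bands) {
  m <- nrow(seg)
  seg <- sweep(seg, 2, colMeans(seg))
  pw <- Mod(stats::mvfft(seg))^2 / m^2
  freqs <- (seq_len(m) - 1) * fs / m
  half <- freqs <= fs / 2
  vapply(bands, function(b) {
    sel <- half & freqs > b[1] & freqs <= b[2]
    sum(pw[sel, ])
  }, numeric(1))
}

#' Spectral-ratio surrogate freeze probabilities
#'
#' Slides a window over each foot's raw tri-axial acceleration, computes
#' periodogram power in the freeze and locomotion bands (summed across
#' axes), maps the ratio `Pf / (Pf + Pl)` through a logistic, and
#' interpolates the window-centre values back onto the session's sample
#' grid. Output is always in \[0, 1\] and deterministic for fixed input.
#'
#' @param session a [fog_session()] carrying raw IMU channels.
#' @param spec a [detector_spec()].
#' @return list with `left` and `right` [probability_trace()] objects at
#'   the session's rate.
#' @export
surrogate_probability <- function(session, spec = detector_spec()) {
  stopifnot(inherits(session, "fog_session"))
  if (is.null(session$raw_imu)) {
    stop("session carries no raw IMU channels (raw_imu missing)",
         call. = FALSE)
  }
  fs <- session$sampling_rate
  n <- length(session$left$values)
  w <- max(4L, as.integer(round(spec$window_s * fs)))
  step <- max(1L, as.integer(round(spec$step_s * fs)))
  if (n < w) {
    stop("session shorter than one detector window", call. = FALSE)
  }
  starts <- seq(1L, n - w + 1L, by = step)
  centers_t <- session$start_time + (starts - 1 + w / 2) / fs
  bands <- list(spec$freeze_band, spec$locomotion_band)
  out <- list()
  for (ft in c("left", "right")) {
    m <- session$raw_imu[[ft]]
    p <- vapply(starts, function(s0) {
      bp <- band_powers(m[s0:(s0 + w - 1L), , drop = FALSE], fs, bands)
      if (sum(bp) < spec$min_power) return(0)
      bp[1] / sum(bp)
    }, numeric(1))
    prob <- stats::plogis(spec$logistic_slope * (p - spec$logistic_midpoint))
    grid_t <- trace_times(session$left)
    vals <- stats::approx(centers_t, prob, xout = grid_t, rule = 2)$y
    out[[ft]] <- probability_trace(pmin(pmax(vals, 0), 1), fs,
                                   start_time = session$start_time, foot = ft)
  }
  out
}

# --- detector registry -----------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Register, list and retrieve detectors
#'
#' A detector is a function mapping a [fog_session()] to
#' `list(left =, right =)` probability traces at the session's rate. The
#' registry lets an external probability source (e.g. CSV output of a real
#' detector pipeline) be wired into [sampling_study()] in place of the
#' built-in surrogate.
#'
#' @param name detector name.
#' @param fun detector function.
#' @return `register_detector()` returns `fun` invisibly; `get_detector()`
#'   the registered function; `list_detectors()` the registered names.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = the_registry)
  invisible(fun)
}

#' @rdname register_detector
#' @export
get_detector <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    stop(sprintf("no detector registered under '%s'", name), call. = FALSE)
  }
  get(name, envir = the_registry, inherits = FALSE)
}

#' @rdname register_detector
#' @export
list_detectors <- function() sort(ls(the_registry))

#' Built-in detectors
#'
#' `surrogate_detector()` wraps [surrogate_probability()] with a fixed
#' spec. `passthrough_detector()` returns the session's own probability
#' traces unchanged -- an ideal detector, useful as a control in
#' sampling-rate studies.
#'
#' @param spec a [detector_spec()].
#' @return a detector function (session -> list(left, right)).
#' @export
surrogate_detector <- function(spec = detector_spec()) {
  force(spec)
  function(session) surrogate_probability(session, spec)
}

#' @rdname surrogate_detector
#' @export
passthrough_detector <- function() {
  function(session) list(left = session$left, right = session$right)
}
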