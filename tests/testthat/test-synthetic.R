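test_that("invalid configurations name the offending field", {
  expect_error(fog_synth_config(sampling_rate = 0), "sampling_rate")
  expect_error(fog_synth_config(ramp_peak_prob = 0.6), "ramp_peak_prob")
  expect_error(fog_synth_config(false_rise_peak = 0.8), "false_rise_peak")
  expect_error(fog_synth_config(ramp_start_prob = 0.99), "ramp_start_prob")
  expect_error(fog_synth_config(freeze_hold = -1), "freeze_hold")
  expect_error(fog_synth_config(tremble_band = c(8, 3)), "tremble_band")
})

test_that("a session with nothing planted stays below 0.7 with empty truth", {
  cfg <- fog_synth_config(seed = 2, freeze_counts = 0, false_rise_rate = 0,
                          baseline_mean = 0.05)
  gs <- generate_session(cfg)
  expect_equal(nrow(gs$annotations), 0L)
  expect_lt(max(gs$session$left$values, gs$session$right$values), 0.7)
  # baseline stays clear of the smallest prediction threshold
  expect_lt(max(gs$session$left$values), 0.2 - 2 * cfg$baseline_sd)
})

test_that("generation is a pure function of the seed", {
  cfg <- fog_synth_config(seed = 33, emit_raw_imu = TRUE)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1, g2)
  g3 <- generate_session(fog_synth_config(seed = 34, emit_raw_imu = TRUE))
  expect_false(identical(g1$session$left$values, g3$session$left$values))
})

test_that("planted freezes are recovered exactly by event detection", {
  # exactly 5 freezes in one long task, zero jitter: detect_events must
  # reproduce the annotations within one sample period per boundary
  plan <- data.frame(task = "Hallway", duration_s = 300, is_sedentary = FALSE)
  cfg <- fog_synth_config(seed = 13, task_plan = plan, freeze_counts = 5,
                          false_rise_rate = 0, annotation_jitter_sd = 0)
  gs <- generate_session(cfg)
  expect_equal(nrow(gs$annotations), 5L)
  ev <- detect_events(combine_feet(gs$session$left, gs$session$right),
                      0.7, 2.0)
  expect_equal(nrow(ev), 5L)
  expect_true(all(abs(ev$start - gs$annotations$start) <= 0.01 + 1e-9))
  expect_true(all(abs(ev$end - gs$annotations$end) <= 0.01 + 1e-9))
  # ramp contract: strictly increasing from ramp start up to onset
  fs <- cfg$sampling_rate
  comb <- combine_feet(gs$session$left, gs$session$right)
  for (k in seq_len(nrow(ev))) {
    on_i <- round(gs$annotations$start[k] * fs)
    seg <- comb$values[(on_i - 20):(on_i)]
    expect_true(all(diff(seg) > 0))
  }
})

test_that("per-event foot assignment leaves the other foot at baseline", {
  plan <- data.frame(task = "GOT", duration_s = 600, is_sedentary = FALSE)
  cfg <- fog_synth_config(seed = 101, task_plan = plan, freeze_counts = 8,
                          false_rise_rate = 0)
  gs <- generate_session(cfg)
  nl <- nrow(detect_events(gs$session$left, 0.7, 2))
  nr <- nrow(detect_events(gs$session$right, 0.7, 2))
  expect_equal(nl + nr, 8L)
  expect_gt(nl, 0L)   # with 8 events a one-sided split is ~0.8 % likely
  expect_gt(nr, 0L)
})

test_that("annotation jitter never inverts or overlaps intervals", {
  cfg <- fog_synth_config(seed = 55, annotation_jitter_sd = 0.3,
                          freezes_per_task = 2)
  gs <- generate_session(cfg)
  ann <- gs$annotations
  expect_true(all(ann$end - ann$start > 0))
  if (nrow(ann) > 1L) {
    expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  }
})

test_that("cohorts derive independent, reproducible participants", {
  cfg <- fog_synth_config(seed = 1)
  co1 <- generate_cohort(cfg, 3, seed = 77)
  co2 <- generate_cohort(cfg, 3, seed = 77)
  expect_identical(co1, co2)
  # pairwise different traces
  expect_false(identical(co1[[1]]$session$left$values,
                         co1[[2]]$session$left$values))
  expect_false(identical(co1[[2]]$session$left$values,
                         co1[[3]]$session$left$values))
  expect_error(generate_cohort(cfg, 0), ">= 1")
})

test_that("planting freezes in a subset yields exactly that many FOG participants", {
  cfg <- fog_synth_config(seed = 1, freezes_per_task = 2)
  co <- generate_cohort(cfg, 20, seed = 99, n_with_fog = 14)
  has_fog <- vapply(co, function(x) nrow(x$annotations) > 0, logical(1))
  expect_equal(sum(has_fog), 14L)
})

test_that("surrogate raw IMU places band power where the state dictates", {
  plan <- data.frame(task = c("Hallway", "Sitting"),
                     duration_s = c(120, 60),
                     is_sedentary = c(FALSE, TRUE))
  cfg <- fog_synth_config(seed = 61, task_plan = plan, freeze_counts = 1,
                          false_rise_rate = 0, emit_raw_imu = TRUE)
  gs <- generate_session(cfg)
  ses <- gs$session
  fs <- ses$sampling_rate
  band_power <- function(x, lo, hi) {
    p <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sum(p[f > lo & f <= hi & f <= fs / 2])
  }
  ann <- gs$annotations
  ft <- if (nrow(detect_events(ses$left, 0.7, 2))) "left" else "right"
  i0 <- round(ann$start[1] * fs) + 5
  i1 <- round(ann$end[1] * fs) - 5
  freeze_seg <- ses$raw_imu[[ft]][i0:i1, 1]
  # trembling band dominates locomotion band during the freeze
  expect_gt(band_power(freeze_seg, 3, 8), band_power(freeze_seg, 0.5, 3))
  # and the reverse during plain walking
  walk_seg <- ses$raw_imu[[ft]][round(5 * fs):round(15 * fs), 1]
  expect_gt(band_power(walk_seg, 0.5, 3), band_power(walk_seg, 3, 8))
  # sedentary stretch is near-silent on every axis
  sed_seg <- ses$raw_imu[[ft]][round(125 * fs):round(175 * fs), ]
  expect_lt(max(abs(sed_seg)), 6 * cfg$noise_sd * cfg$sedentary_scale)
  # standalone synthesis is deterministic
  ses2 <- synthesize_raw_imu(fog_session(ses$left, ses$right,
                                         ses$active_mask, ses$segments), cfg)
  ses3 <- synthesize_raw_imu(fog_session(ses$left, ses$right,
                                         ses$active_mask, ses$segments), cfg)
  expect_identical(ses2$raw_imu, ses3$raw_imu)
  cfg_no <- fog_synth_config(seed = 61, emit_raw_imu = FALSE)
  expect_error(synthesize_raw_imu(ses, cfg_no), "emit_raw_imu")
})

test_that("sedentary-only sessions produce raw power below the noise floor", {
  plan <- data.frame(task = "Sitting", duration_s = 60, is_sedentary = TRUE)
  cfg <- fog_synth_config(seed = 71, task_plan = plan, freeze_counts = 0,
                          false_rise_rate = 0, emit_raw_imu = TRUE)
  ses <- generate_session(cfg)$session
  expect_lt(stats::sd(ses$raw_imu$left[, 1]), cfg$noise_sd)
})
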