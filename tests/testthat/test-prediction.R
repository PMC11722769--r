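test_that("pre-onset window extraction returns [onset - w, onset)", {
  tr <- probability_trace(rep(0.1, 100), 10)
  expect_length(extract_pre_onset_window(tr, 3.0, 3.0)$values, 30)
  expect_length(extract_pre_onset_window(tr, 1.0, 3.0)$values, 10)  # truncated
  w <- extract_pre_onset_window(tr, 5.0, 2.0)
  expect_true(all(w$values == 0.1))
  expect_error(extract_pre_onset_window(tr, -1, 3), "before")
})

test_that("monotone crossings require a rise from below through the threshold", {
  cfg <- prediction_config(min_run_s = 0.2, refractory_s = 0)
  # linear rise 0.1 -> 0.9 over 2 s: exactly one crossing of 0.35
  fs <- 20
  v <- seq(0.1, 0.9, length.out = 2 * fs)
  cr <- find_monotone_crossings(probability_trace(v, fs), 0.35, cfg)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$time, (min(which(v > 0.35)) - 1) / fs)

  # constant 0.5 never rises from <= threshold
  cr <- find_monotone_crossings(probability_trace(rep(0.5, 40), fs), 0.35, cfg)
  expect_equal(nrow(cr), 0L)

  # worked example at 10 Hz: crossings at sample indices 2 and 6 (0-based)
  v <- c(0.1, 0.2, 0.4, 0.3, 0.2, 0.3, 0.4)
  cr <- find_monotone_crossings(probability_trace(v, 10), 0.35, cfg)
  expect_equal(cr$time, c(0.2, 0.6))
  expect_true(all(cr$run_length_s >= 0.2))

  # a short run below min_run_s is rejected
  cfg2 <- prediction_config(min_run_s = 0.5, refractory_s = 0)
  cr <- find_monotone_crossings(probability_trace(v, 10), 0.35, cfg2)
  expect_equal(nrow(cr), 0L)
})

test_that("crossings match the exhaustive run-scan oracle on random traces", {
  set.seed(202)
  for (rep in 1:50) {
    fs <- 10
    v <- round(stats::runif(60), 2)
    thr <- stats::runif(1, 0.2, 0.6)
    min_run <- sample(c(0, 0.1, 0.3), 1)
    refr <- sample(c(0, 0.5, 1), 1)
    cfg <- prediction_config(min_run_s = min_run, refractory_s = refr)
    got <- find_monotone_crossings(probability_trace(v, fs), thr, cfg)$time
    want <- oracle_crossings(v, fs, thr, min_run, refr)
    expect_equal(got, want)
  }
})

test_that("refractory period suppresses rapid repeat crossings", {
  fs <- 10
  v <- rep(c(0.1, 0.2, 0.5), 5)  # rises through 0.35 every 0.3 s
  cfg0 <- prediction_config(min_run_s = 0, refractory_s = 0)
  cfg1 <- prediction_config(min_run_s = 0, refractory_s = 1)
  n0 <- nrow(find_monotone_crossings(probability_trace(v, fs), 0.35, cfg0))
  n1 <- nrow(find_monotone_crossings(probability_trace(v, fs), 0.35, cfg1))
  expect_equal(n0, 5L)
  expect_equal(n1, 2L)   # t = 0.2 and t = 1.4
})

test_that("a 3 s ramp is predicted at low thresholds and not at 0.5", {
  # ramp 0.05 -> 0.95 over 3 s: onset (0.7-crossing) 2.167 s after ramp
  # start; crossing of tau leads the onset by 3 * (0.7 - tau) / 0.9
  tr <- make_ramp_trace(fs = 100, ramp_start = 5)
  ev <- detect_events(tr, 0.7, 2.0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 5 + 3 * 0.65 / 0.9, tolerance = 0.011)
  cfg <- prediction_config()
  p02 <- evaluate_predictions(tr, ev, 0.2, cfg)   # lead 1.667 s >= 1
  expect_equal(p02$true_rate, 1)
  expect_equal(p02$n_false_crossings, 0L)
  p05 <- evaluate_predictions(tr, ev, 0.5, cfg)   # lead 0.667 s < 1
  expect_equal(p05$true_rate, 0)
  expect_equal(p05$false_rate, 0)                 # onset within fp horizon
  # with lead_min relaxed to 0 the same crossing counts
  cfg0 <- prediction_config(lead_min_s = 0)
  expect_equal(evaluate_predictions(tr, ev, 0.5, cfg0)$true_rate, 1)
})

test_that("sub-threshold false rises are counted as false alarms", {
  # rise to 0.6 and back: crossings of 0.35 but never an event
  fs <- 100
  t <- (0:(20 * fs - 1)) / fs
  v <- rep(0.05, length(t))
  i <- t >= 5 & t < 8
  v[i] <- 0.05 + (0.6 - 0.05) * (t[i] - 5) / 3
  i <- t >= 8 & t < 9
  v[i] <- 0.6 - 0.55 * (t[i] - 8)
  tr <- probability_trace(v, fs)
  ev <- detect_events(tr, 0.7, 2.0)
  expect_equal(nrow(ev), 0L)
  pc <- evaluate_predictions(tr, ev, 0.35, prediction_config())
  expect_equal(pc$n_events, 0L)
  expect_equal(pc$n_false_crossings, 1L)
  expect_equal(pc$false_rate, 1)
  expect_true(is.na(pc$true_rate))   # empty denominator reported absent
})

test_that("no crossings with events yields true_rate 0 and absent false_rate", {
  tr <- probability_trace(c(rep(0.8, 50), rep(0.05, 50)), 10)  # starts high
  ev <- detect_events(tr, 0.7, 2.0)
  expect_equal(nrow(ev), 1L)
  pc <- evaluate_predictions(tr, ev, 0.35, prediction_config())
  expect_equal(pc$n_crossings, 0L)
  expect_equal(pc$true_rate, 0)
  expect_true(is.na(pc$false_rate))
})

test_that("crossings inside an ongoing event are discarded", {
  # deep dip inside a merged episode re-crosses 0.35 while still inside the
  # event interval; that crossing must not be counted
  fs <- 100
  v <- c(rep(0.05, 200), seq(0.05, 0.95, length.out = 300), rep(0.95, 100),
         seq(0.95, 0.2, length.out = 50), seq(0.2, 0.95, length.out = 50),
         rep(0.95, 100), seq(0.95, 0.05, length.out = 100), rep(0.05, 100))
  tr <- probability_trace(v, fs)
  ev <- detect_events(tr, 0.7, 2.0)
  expect_equal(nrow(ev), 1L)   # sub-2 s dip is merged into one episode
  pc <- evaluate_predictions(tr, ev, 0.35, prediction_config())
  expect_equal(pc$n_crossings, 1L)   # only the pre-onset ramp crossing
  expect_equal(pc$true_rate, 1)
})

test_that("threshold sweep is non-increasing on ramp cohorts and flags false-rise-only cohorts", {
  cfg <- fog_synth_config(seed = 11, false_rise_rate = 1)
  cohort <- generate_cohort(cfg, 4, seed = 23)
  sw <- threshold_sweep(cohort)
  expect_equal(nrow(sw), 7L)
  expect_true(all(diff(sw$true_rate_mean) <= 1e-12))
  expect_true(all(sw$true_rate_mean >= 0 & sw$true_rate_mean <= 1))
  expect_true(all(sw$false_rate_mean >= 0 & sw$false_rate_mean <= 1,
                  na.rm = TRUE))

  # all events predicted at every threshold -> mean 1, SD 0 (no false rises,
  # lead_min 0 keeps even the 0.5-threshold lead qualifying)
  cfg2 <- fog_synth_config(seed = 5, false_rise_rate = 0, freeze_counts = 1)
  cohort2 <- generate_cohort(cfg2, 2, seed = 31)
  sw2 <- threshold_sweep(cohort2, prediction_config(lead_min_s = 0))
  expect_true(all(sw2$true_rate_mean == 1))
  expect_true(all(sw2$true_rate_sd == 0))

  # false rises only: false rate 1 everywhere, no events anywhere
  cfg3 <- fog_synth_config(seed = 9, freeze_counts = 0, false_rise_rate = 3)
  cohort3 <- generate_cohort(cfg3, 3, seed = 37)
  sw3 <- threshold_sweep(cohort3)
  expect_true(all(is.na(sw3$true_rate_mean)))
  expect_true(all(sw3$false_rate_mean == 1))

  expect_error(threshold_sweep(list()), "non-empty")
})

test_that("sweep determinism: identical cohorts give identical tables", {
  cfg <- fog_synth_config(seed = 3, false_rise_rate = 2)
  s1 <- threshold_sweep(generate_cohort(cfg, 3, seed = 13))
  s2 <- threshold_sweep(generate_cohort(cfg, 3, seed = 13))
  expect_identical(s1, s2)
})
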