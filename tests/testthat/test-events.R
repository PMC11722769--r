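test_that("combine_feet takes the pointwise either-foot maximum", {
  l <- probability_trace(c(0.1, 0.8, 0.2), 10, foot = "left")
  r <- probability_trace(c(0.9, 0.1, 0.2), 10, foot = "right")
  expect_equal(combine_feet(l, r)$values, c(0.9, 0.8, 0.2))
  expect_equal(combine_feet(l, l)$values, l$values)   # idempotent
  z <- probability_trace(rep(0, 3), 10, foot = "left")
  h <- probability_trace(rep(0.8, 3), 10, foot = "right")
  expect_equal(combine_feet(z, h)$values, rep(0.8, 3))
  bad <- probability_trace(c(0.1, 0.2), 10, foot = "right")
  expect_error(combine_feet(l, bad), "length")
  bad_rate <- probability_trace(c(0.1, 0.2, 0.3), 20, foot = "right")
  expect_error(combine_feet(l, bad_rate), "sampling rate")
})

test_that("detect_events thresholds strictly and merges sub-2 s gaps", {
  # all at or below threshold: nothing (ties are non-freeze)
  tr <- probability_trace(rep(0.7, 50), 10)
  expect_equal(nrow(detect_events(tr)), 0L)

  # runs [1.0,1.5) and [2.0,2.5) at 10 Hz: gap 0.5 < 2 merges into one
  v <- rep(0.1, 50)
  v[11:15] <- 0.9
  v[21:25] <- 0.9
  ev <- detect_events(probability_trace(v, 10), 0.7, 2.0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 1.0)
  expect_equal(ev$end, 2.5)

  # runs [1.0,1.5) and [4.0,4.5): gap 2.5 >= 2 stays split
  v <- rep(0.1, 60)
  v[11:15] <- 0.9
  v[41:45] <- 0.9
  ev <- detect_events(probability_trace(v, 10), 0.7, 2.0)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start, c(1.0, 4.0))

  # gap of exactly merge_gap stays split (strict comparison)
  v <- rep(0.1, 60)
  v[11:15] <- 0.9
  v[36:40] <- 0.9    # gap = 2.0 s
  ev <- detect_events(probability_trace(v, 10), 0.7, 2.0)
  expect_equal(nrow(ev), 2L)
})

test_that("detect_events matches the brute-force oracle on random traces", {
  set.seed(101)
  for (rep in 1:60) {
    fs <- sample(c(10, 20, 32), 1)
    thr <- stats::runif(1, 0.3, 0.8)
    gap <- stats::runif(1, 0, 3)
    tr <- random_trace(fs = fs, dur_s = 10)
    got <- detect_events(tr, thr, gap)
    want <- oracle_detect_events(tr$values, fs, thr, gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start, tolerance = 1e-9)
      expect_equal(got$end, want$end, tolerance = 1e-9)
    }
    if (nrow(got) > 1L) {
      expect_true(all(got$start[-1] - got$end[-nrow(got)] >= gap - 1e-9))
    }
  }
})

test_that("raising the threshold never increases supra-threshold time", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_trace(fs = 20, dur_s = 15)
    time_above <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th) {
      ev <- detect_events(tr, th, merge_gap = 0)
      if (nrow(ev)) sum(ev$end - ev$start) else 0
    }, numeric(1))
    expect_true(all(diff(time_above) <= 1e-12))
  }
})

test_that("classify_time counts sample-wise confusion over active time", {
  # identity: algo == truth, all active
  iv <- fog_intervals(c(2, 10), c(5, 12), source = "video")
  algo <- fog_intervals(c(2, 10), c(5, 12), source = "algorithm")
  conf <- classify_time(algo, iv, rep(TRUE, 200), 10)
  expect_equal(conf$fp_s, 0)
  expect_equal(conf$fn_s, 0)
  expect_equal(conf$tp_s, 5)

  # empty algo, 6 s of truth in a 60 s active session
  conf <- classify_time(fog_intervals(source = "algorithm"),
                        fog_intervals(20, 26), rep(TRUE, 600), 10)
  expect_equal(conf$fn_s, 6)
  expect_equal(conf$tn_s, 54)

  # worked overlap: algo [2,5), truth [4,8), 10 s @ 10 Hz
  conf <- classify_time(fog_intervals(2, 5, source = "algorithm"),
                        fog_intervals(4, 8), rep(TRUE, 100), 10)
  expect_equal(conf$tp_s, 1)
  expect_equal(conf$fp_s, 2)
  expect_equal(conf$fn_s, 3)
  expect_equal(conf$tn_s, 4)

  # interval outside the span errors
  expect_error(
    classify_time(fog_intervals(2, 15, source = "algorithm"),
                  fog_intervals(4, 8), rep(TRUE, 100), 10),
    "outside")
})

test_that("confusion conserves analyzed time and swaps fp/fn symmetrically", {
  set.seed(42)
  for (rep in 1:40) {
    span <- 30
    fs <- 10
    algo <- random_intervals(span, sample(0:4, 1), source = "algorithm")
    truth <- random_intervals(span, sample(0:4, 1))
    mask <- stats::runif(span * fs) > 0.3
    c1 <- classify_time(algo, truth, mask, fs)
    expect_equal(c1$tp_s + c1$fp_s + c1$tn_s + c1$fn_s, c1$analyzed_s)
    expect_equal(c1$analyzed_s, sum(mask) / fs)
    c2 <- classify_time(truth, algo, mask, fs)
    expect_equal(c1$fp_s, c2$fn_s)
    expect_equal(c1$fn_s, c2$fp_s)
    expect_equal(c1$tp_s, c2$tp_s)
    # and against the per-sample loop oracle
    want <- oracle_classify(algo, truth, mask, fs)
    expect_equal(c1$tp_s, unname(want["tp"]))
    expect_equal(c1$fp_s, unname(want["fp"]))
    expect_equal(c1$tn_s, unname(want["tn"]))
    expect_equal(c1$fn_s, unname(want["fn"]))
  }
})
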