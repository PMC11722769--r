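test_that("accuracy is the (TP + TN) share of analyzed time", {
  expect_equal(accuracy(fog_confusion(10, 5, 80, 5, 100)), 90)
  expect_equal(accuracy(fog_confusion(6, 0, 54, 0, 60)), 100)
  # disjoint algo (3 s) and truth (4 s) in a 10 s session: only 3 s TN
  conf <- classify_time(fog_intervals(0, 3, source = "algorithm"),
                        fog_intervals(4, 8), rep(TRUE, 100), 10)
  expect_equal(accuracy(conf), 30)
  expect_error(accuracy(fog_confusion(0, 0, 0, 0, 0)), "zero")
})

test_that("accuracy is invariant under swapping the algorithm and truth roles", {
  set.seed(77)
  for (rep in 1:15) {
    algo <- random_intervals(20, 3, source = "algorithm")
    truth <- random_intervals(20, 3)
    mask <- stats::runif(200) > 0.2
    a1 <- accuracy(classify_time(algo, truth, mask, 10))
    a2 <- accuracy(classify_time(truth, algo, mask, 10))
    expect_equal(a1, a2)
  }
})

test_that("%WTSF divides masked freeze time by active time", {
  mask <- rep(TRUE, 600)            # 60 s at 10 Hz
  ev <- fog_intervals(10, 16, source = "algorithm")
  expect_equal(wtsf(ev, mask, 10), 10)
  expect_equal(wtsf(fog_intervals(source = "algorithm"), mask, 10), 0)
  # event half inside a sedentary block counts only its active half
  mask2 <- rep(TRUE, 600)
  mask2[301:600] <- FALSE
  ev2 <- fog_intervals(28, 32, source = "algorithm")
  expect_equal(wtsf(ev2, mask2, 10), 100 * 2 / 30)
  expect_error(wtsf(ev, rep(FALSE, 600), 10), "active")
})

test_that("per-task metrics pool time, not percentages", {
  # two equal 30 s tasks at 10 Hz; task A fully correct, task B 60% correct
  # (6 s FP + 6 s FN of 30 s), so pooled overall is 80%, not mean(100, 60)
  segs <- fog_segments(c("Hallway", "GOT"), c(0, 30), c(30, 60))
  l <- probability_trace(rep(0.05, 600), 10, foot = "left")
  r <- probability_trace(rep(0.05, 600), 10, foot = "right")
  ses <- fog_session(l, r, rep(TRUE, 600), segments = segs)
  truth <- fog_intervals(c(5, 35), c(11, 41))
  algo <- fog_intervals(c(5, 41), c(11, 47), source = "algorithm")
  rep_ <- per_task_metrics(ses, algo, truth)
  expect_equal(rep_$per_task$accuracy_pct,
               c(100, 100 * (30 - 12) / 30))
  expect_equal(rep_$overall_pct, 80)
  expect_equal(rep_$overall_pct,
               sum(rep_$per_task$accuracy_pct * rep_$per_task$analyzed_s) /
                 sum(rep_$per_task$analyzed_s))
  # one-task session: per-task equals overall
  segs1 <- fog_segments("Hallway", 0, 60)
  ses1 <- fog_session(l, r, rep(TRUE, 600), segments = segs1)
  rep1 <- per_task_metrics(ses1, algo, truth)
  expect_equal(rep1$per_task$accuracy_pct, rep1$overall_pct)
})

test_that("sedentary tasks are absent and unsegmented samples warn", {
  segs <- fog_segments(c("Hallway", "Sitting"), c(0, 30), c(30, 55),
                       is_sedentary = c(FALSE, TRUE))
  mask <- c(rep(TRUE, 300), rep(FALSE, 250), rep(TRUE, 50))  # 5 s orphaned
  l <- probability_trace(rep(0.05, 600), 10, foot = "left")
  r <- probability_trace(rep(0.05, 600), 10, foot = "right")
  ses <- fog_session(l, r, mask, segments = segs)
  expect_warning(
    rep_ <- per_task_metrics(ses, fog_intervals(source = "algorithm"),
                             fog_intervals()),
    "outside all segments")
  expect_false("Sitting" %in% rep_$per_task$task)
  expect_equal(rep_$confusion$analyzed_s, 30)
})

test_that("category aggregates pool clinic FOG vs IADL time", {
  segs <- fog_segments(c("Hallway", "Vacuuming"), c(0, 30), c(30, 60))
  expect_equal(segs$category, c("clinic_fog", "iadl"))
  l <- probability_trace(rep(0.05, 600), 10, foot = "left")
  ses <- fog_session(l, l, rep(TRUE, 600), segments = segs)
  truth <- fog_intervals(5, 11)
  rep_ <- per_task_metrics(ses, fog_intervals(source = "algorithm"), truth)
  pc <- rep_$per_category
  expect_equal(sort(pc$category), c("clinic_fog", "iadl"))
  expect_equal(pc$accuracy_pct[pc$category == "clinic_fog"], 80)
  expect_equal(pc$accuracy_pct[pc$category == "iadl"], 100)
})

test_that("task potency counts participants and sums overlapped duration", {
  segs <- fog_segments(c("GOT-DT", "Hallway"), c(0, 60), c(60, 120))
  # no annotations anywhere: all rows zero
  pot0 <- task_potency(list(fog_intervals(), fog_intervals()),
                       list(segs, segs))
  expect_true(all(pot0$n_participants_with_fog == 0))
  expect_true(all(pot0$total_fog_duration_s == 0))

  # 19 participants, 16 with a freeze inside GOT-DT
  anns <- lapply(1:19, function(i) {
    if (i <= 16) fog_intervals(10, 14) else fog_intervals()
  })
  pot <- task_potency(anns, replicate(19, segs, simplify = FALSE))
  row <- pot[pot$task == "GOT-DT", ]
  expect_equal(row$n_participants_with_fog, 16L)
  expect_equal(round(row$pct_of_sample), 84)
  expect_equal(row$total_fog_duration_s, 16 * 4)

  # a 5 s freeze spanning a boundary splits 3 s / 2 s across tasks
  pot2 <- task_potency(list(fog_intervals(57, 62)), list(segs))
  expect_equal(pot2$total_fog_duration_s[pot2$task == "GOT-DT"], 3)
  expect_equal(pot2$total_fog_duration_s[pot2$task == "Hallway"], 2)
  expect_equal(sum(pot2$n_participants_with_fog), 2L)
})
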