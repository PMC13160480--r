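test_that("three raised-cosine bumps segment into three repetitions at the bump centers", {
  spec <- trajectory_spec(task_id = 1, peak_angles_deg = c(90, 90, 90),
                          rest_s = 10, bump_duration_s = 4, fps = 30,
                          seed = 61)
  sim <- simulate_task_trajectory(spec)
  sh <- shoulder_angle_series(sim$sequence, "right")
  segs <- segment_repetitions(sh, expected = 3)
  expect_equal(nrow(segs), 3)
  expect_false(attr(segs, "mismatch"))
  # bump r spans [10 + 14(r-1), 14 + 14(r-1)] s; centers at 12, 26, 40 s
  centers <- (c(12, 26, 40)) * 30
  expect_true(all(abs(segs$peak_frame - centers) <= 1))
  expect_equal(segs$peak_angle_deg, rep(90, 3), tolerance = 1e-6)
})

test_that("flat series yields zero segments with a mismatch flag; small wiggles are filtered by prominence", {
  flat <- series_from_values(rep(10, 600))
  segs <- segment_repetitions(flat, expected = 3)
  expect_equal(nrow(segs), 0)
  expect_true(attr(segs, "mismatch"))

  # 3 large bumps + one 3-degree wiggle: prominence 10 keeps exactly 3
  fps <- 30
  t <- (0:(52 * fps - 1)) / fps
  x <- rep(5, length(t))
  bump <- function(x, t0, dur, amp) {
    inb <- t >= t0 & t <= t0 + dur
    x[inb] <- x[inb] + amp * (1 - cos(2 * pi * (t[inb] - t0) / dur)) / 2
    x
  }
  x <- bump(x, 10, 4, 85); x <- bump(x, 24, 4, 85); x <- bump(x, 38, 4, 85)
  x <- bump(x, 45, 2, 3)   # sub-prominence wiggle
  sr <- series_from_values(x, fps = fps)
  segs <- segment_repetitions(sr, expected = 3, min_prominence_deg = 10)
  expect_equal(nrow(segs), 3)
  expect_false(attr(segs, "mismatch"))
})

test_that("segmentation recovers count and peaks over randomized generator settings", {
  set.seed(62)
  for (i in 1:6) {
    amp <- runif(1, 30, 150)
    rest <- runif(1, 5, 15)
    noise <- sample(c(0, 2), 1)
    spec <- trajectory_spec(task_id = 1, peak_angles_deg = rep(amp, 3),
                            baseline_shoulder_deg = 5, rest_s = rest,
                            bump_duration_s = 4, noise_px = noise,
                            seed = 100 + i)
    sim <- simulate_task_trajectory(spec)
    sh <- smooth_series(gate_by_visibility(
      shoulder_angle_series(sim$sequence, "right"), sim$sequence), 5)
    segs <- segment_repetitions(sh, expected = 3)
    expect_equal(nrow(segs), 3)
    truth_peaks <- which(diff(sign(diff(sim$truth$shoulder$samples$angle_deg))) == -2)
    tol_frames <- if (noise == 0) 1 else 0.5 * 30  # flat top + jitter
    expect_true(all(abs(segs$peak_frame - truth_peaks) <= tol_frames))
  }
})

test_that("peak and excursion ROM read the segment correctly", {
  fps <- 30
  t <- (0:(30 * fps - 1)) / fps
  x <- rep(5, length(t))
  inb <- t >= 10 & t <= 14
  x[inb] <- 5 + 90 * (1 - cos(2 * pi * (t[inb] - 10) / 4)) / 2
  sr <- series_from_values(x, fps = fps)
  segs <- segment_repetitions(sr, expected = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(peak_rom(segs[1, ], sr, mode = "peak"), 95, tolerance = 1e-6)
  expect_equal(peak_rom(segs[1, ], sr, mode = "excursion"), 90,
               tolerance = 1e-3)
})

test_that("simulator per-repetition peaks are recovered within 0.5 degrees", {
  spec <- trajectory_spec(task_id = 1, peak_angles_deg = c(100, 105, 98),
                          seed = 63)
  sim <- simulate_task_trajectory(spec)
  out <- summarize_recording(sim$sequence, default_task_registry()[["1"]],
                             "right", rom_config())
  expect_equal(out$shoulder$rep_values, c(100, 105, 98), tolerance = 0.5 / 100)
  expect_equal(out$shoulder$mean_rom, mean(out$shoulder$rep_values))
})

test_that("joints summarized follow the task definition; task 1 never emits an elbow summary", {
  reg <- default_task_registry()
  sims <- lapply(1:4, function(id) {
    simulate_task_trajectory(trajectory_spec(task_id = id, rest_s = 5,
                                             bump_duration_s = 3,
                                             seed = 70 + id))
  })
  s1 <- summarize_recording(sims[[1]]$sequence, reg[["1"]], "right")
  expect_named(s1, "shoulder")
  s2 <- summarize_recording(sims[[2]]$sequence, reg[["2"]], "right")
  expect_setequal(names(s2), c("shoulder", "elbow"))
  total <- sum(vapply(1:4, function(id)
    length(summarize_recording(sims[[id]]$sequence, reg[[as.character(id)]],
                               "right")), integer(1)))
  expect_equal(total, 7)  # 1 + 2 + 2 + 2
})

test_that("elbow flexion minima are extracted with the min extremum direction", {
  spec <- trajectory_spec(task_id = 3, elbow_min_deg = c(40, 45, 42),
                          seed = 72)
  sim <- simulate_task_trajectory(spec)
  out <- summarize_recording(sim$sequence, default_task_registry()[["3"]],
                             "right", rom_config())
  expect_equal(out$elbow$rep_values, c(40, 45, 42), tolerance = 0.5 / 40)
})

test_that("mean ROM is the exact permutation-invariant mean of repetition values", {
  set.seed(73)
  vals <- runif(3, 40, 150)
  expect_equal(mean(vals), mean(sample(vals)))
  spec <- trajectory_spec(task_id = 1, peak_angles_deg = sort(vals),
                          seed = 74)
  sim <- simulate_task_trajectory(spec)
  out <- summarize_recording(sim$sequence, default_task_registry()[["1"]],
                             "right")
  expect_identical(out$shoulder$mean_rom, mean(out$shoulder$rep_values))
})

test_that("ROM CSV carries one row per repetition plus an aggregate row", {
  spec <- trajectory_spec(task_id = 2, seed = 75)
  sim <- simulate_task_trajectory(spec)
  out <- summarize_recording(sim$sequence, default_task_registry()[["2"]],
                             "right")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rom_csv(out, path, participant = "p7")
  d <- read.csv(path)
  expect_equal(nrow(d), 2 * (3 + 1))  # two joints x (3 reps + mean)
  expect_setequal(unique(d$joint), c("shoulder", "elbow"))
  means <- d[d$rep == "mean", ]
  for (j in c("shoulder", "elbow")) {
    expect_equal(means$rom_deg[means$joint == j],
                 mean(d$rom_deg[d$joint == j & d$rep != "mean"]))
  }
})
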