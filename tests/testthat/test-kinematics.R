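test_that("interior angle matches analytic values", {
  expect_equal(joint_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(joint_angle(c(0, 1), c(0, 0), c(0, -1)), 180)
  expect_equal(joint_angle(c(2, 0), c(0, 0), c(1, 1)), 45)
  # symmetry in the outer points
  set.seed(11)
  for (i in 1:20) {
    p <- matrix(rnorm(6, 0, 100), 3, 2)
    expect_equal(joint_angle(p[1, ], p[2, ], p[3, ]),
                 joint_angle(p[3, ], p[2, ], p[1, ]))
  }
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 0)), "zero-length ray")
})

test_that("angle is invariant under similarity transforms to 1e-7 degrees", {
  set.seed(12)
  max_dev <- 0
  for (i in 1:1000) {
    pts <- matrix(rnorm(6, 0, 10), 3, 2)
    if (min(sqrt(rowSums((pts[c(1, 3), ] -
                            pts[c(2, 2), ])^2))) < 1e-3) next
    a0 <- joint_angle(pts[1, ], pts[2, ], pts[3, ])
    tp <- similarity_transform(pts, angle = runif(1, 0, 2 * pi),
                               scale = exp(runif(1, -2, 2)),
                               shift = rnorm(2, 0, 100))
    a1 <- joint_angle(tp[1, ], tp[2, ], tp[3, ])
    max_dev <- max(max_dev, abs(a1 - a0))
  }
  expect_lt(max_dev, 1e-7)
})

test_that("near-collinear triples are clamped, never NaN", {
  eps <- 1e-13
  a <- joint_angle(c(1, eps), c(0, 0), c(-1, eps))
  expect_true(is.finite(a))
  expect_true(a >= 0 && a <= 180)
})

test_that("shoulder and elbow series reproduce canonical poses", {
  # arm hanging parallel to the trunk: shoulder ~ 0 degrees
  sq <- posed_sequence(shoulder = c(900, 450), elbow = c(900, 630),
                       wrist = c(900, 790), hip = c(900, 700))
  sh <- shoulder_angle_series(sq, "right")
  expect_equal(sh$samples$angle_deg, 0)
  el <- elbow_angle_series(sq, "right")
  expect_equal(el$samples$angle_deg, 180)  # straight arm, full extension

  # elbow horizontal from shoulder, hip vertical below: shoulder 90 degrees
  sq2 <- posed_sequence(shoulder = c(900, 450), elbow = c(1080, 450),
                        wrist = c(1080, 610), hip = c(900, 700))
  expect_equal(shoulder_angle_series(sq2, "right")$samples$angle_deg, 90)
  expect_equal(elbow_angle_series(sq2, "right")$samples$angle_deg, 90)
})

test_that("series computation demands pixel space and known landmarks", {
  d <- constant_pose_data(2)
  d$x <- d$x / 2000; d$y <- d$y / 2000
  sq <- landmark_sequence(d, fps = 30, normalized = TRUE)
  expect_error(shoulder_angle_series(sq, "right"), "normalize_to_pixels")
})

test_that("visibility gating interpolates short gaps and rejects long ones", {
  spec <- trajectory_spec(task_id = 1, rest_s = 2, bump_duration_s = 2,
                          n_reps = 1, peak_angles_deg = 90, seed = 21)
  sim <- simulate_task_trajectory(spec)
  seq <- sim$sequence

  # all visibilities 1: gating changes nothing
  sh <- shoulder_angle_series(seq, "right")
  gated <- gate_by_visibility(sh, seq, threshold = 0.5, max_gap_frames = 5)
  expect_equal(gated$samples$angle_deg, sh$samples$angle_deg)
  expect_true(all(!gated$samples$interpolated))

  # single-frame dropout mid-movement: linear midpoint of the neighbours
  seq1 <- seq
  mid <- 75L  # inside the bump
  sel <- seq1$data$frame == mid & seq1$data$landmark == "right_elbow"
  seq1$data$visibility[sel] <- 0.1
  sh1 <- gate_by_visibility(shoulder_angle_series(seq1, "right"), seq1)
  s <- sh1$samples
  expect_true(s$interpolated[s$frame == mid])
  expect_equal(s$angle_deg[s$frame == mid],
               (s$angle_deg[s$frame == mid - 1] +
                  s$angle_deg[s$frame == mid + 1]) / 2)

  # 10-frame dropout with max_gap_frames = 5 stays invalid
  seq2 <- seq
  sel2 <- seq2$data$frame %in% 70:79 & seq2$data$landmark == "right_elbow"
  seq2$data$visibility[sel2] <- 0
  sh2 <- gate_by_visibility(shoulder_angle_series(seq2, "right"), seq2,
                            max_gap_frames = 5)
  expect_equal(sum(!sh2$samples$valid), 10)
})

test_that("moving-average smoothing is identity at window 1, idempotent on constants, and reduces white-noise variance ~window-fold", {
  const <- series_from_values(rep(42, 100))
  expect_equal(smooth_series(const, 5)$samples$angle_deg, rep(42, 100))

  set.seed(31)
  noise <- series_from_values(90 + rnorm(1000, 0, 3))
  expect_identical(smooth_series(noise, 1), noise)
  sm <- smooth_series(noise, 5)
  ratio <- var(sm$samples$angle_deg) / var(noise$samples$angle_deg)
  expect_lt(abs(ratio - 1 / 5), 0.3 / 5)
  expect_error(smooth_series(noise, 4), "odd")
})

test_that("kinematics round-trips the simulator ground truth", {
  # noise-free: exact inverse within 1e-6 degrees at window 1
  spec <- trajectory_spec(task_id = 3, peak_angles_deg = c(100, 105, 98),
                          elbow_min_deg = c(40, 45, 50), seed = 41)
  sim <- simulate_task_trajectory(spec)
  sh <- shoulder_angle_series(sim$sequence, "right")
  el <- elbow_angle_series(sim$sequence, "right")
  expect_lt(max(abs(sh$samples$angle_deg -
                      sim$truth$shoulder$samples$angle_deg)), 1e-6)
  expect_lt(max(abs(el$samples$angle_deg -
                      sim$truth$elbow$samples$angle_deg)), 1e-6)
  # series extrema match the prescribed profile after smoothing
  sm <- smooth_series(sh, 5)
  expect_lt(abs(max(sm$samples$angle_deg) - 105), 0.5)
  sme <- smooth_series(el, 5)
  expect_lt(abs(min(sme$samples$angle_deg) - 40), 0.5)
})

test_that("angle CSV round-trips joints, sides and validity flags", {
  spec <- trajectory_spec(task_id = 2, rest_s = 2, bump_duration_s = 2,
                          n_reps = 1, seed = 51)
  sim <- simulate_task_trajectory(spec)
  sh <- shoulder_angle_series(sim$sequence, "right")
  el <- elbow_angle_series(sim$sequence, "right")
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_csv(list(sh, el), path)
  back <- read_angle_csv(path)
  expect_setequal(names(back), c("shoulder_right", "elbow_right"))
  expect_equal(back$shoulder_right$samples$angle_deg,
               sh$samples$angle_deg, tolerance = 1e-4)
  expect_equal(back$elbow_right$samples$valid, el$samples$valid)
})
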