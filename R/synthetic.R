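# Ground-truth generators: forward-kinematic task trajectories (the inverse
# of the angle computation, establishing the module-pair oracle) and
# paired-rater / two-way measurement data with known bias, LoA and ICC.

#' Specification of a synthetic task trajectory
#'
#' Describes one recording of a clinical task: a planar three-segment
#' kinematic chain (trunk, upper arm, forearm) animated by raised-cosine
#' angle bumps -- smooth, compactly supported profiles whose peak value is
#' known analytically. Defaults mirror the nominal recording protocol:
#' 3 repetitions separated by 10 s of rest, 30 frames per second, a
#' 1920 x 1080 frame, and segment lengths (trunk 250 px, upper arm 180 px,
#' forearm 160 px) plausible for an adult filmed at 1.5 m.
#'
#' @param task_id Task id resolved against `registry`.
#' @param side `"left"` or `"right"` (the animated arm).
#' @param fps Frames per second.
#' @param rest_s Rest between repetitions, seconds.
#' @param n_reps Number of repetitions.
#' @param peak_angles_deg Per-repetition peak shoulder angle, degrees in
#'   (0, 180); recycled if scalar.
#' @param elbow_min_deg Per-repetition minimum elbow angle during flexion
#'   (only used when the task measures the elbow); recycled if scalar.
#' @param bump_duration_s Duration of one movement bump, seconds.
#' @param baseline_shoulder_deg Resting shoulder angle (arm hanging).
#' @param baseline_elbow_deg Resting elbow angle (near full extension).
#' @param trunk_px,upper_arm_px,forearm_px Segment lengths in pixels.
#' @param noise_px Isotropic Gaussian landmark jitter SD in pixels,
#'   applied after exact placement.
#' @param dropout_prob Per frame x landmark probability of visibility 0.
#' @param image_width_px,image_height_px Frame geometry.
#' @param seed Integer seed; the generator is deterministic given the seed,
#'   which is recorded in the sequence metadata.
#' @param registry Task registry (see [default_task_registry()]).
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(task_id = 1, side = "right", fps = 30,
                            rest_s = 10, n_reps = 3,
                            peak_angles_deg = c(100, 105, 98),
                            elbow_min_deg = c(60, 55, 65),
                            bump_duration_s = 4,
                            baseline_shoulder_deg = 5,
                            baseline_elbow_deg = 175,
                            trunk_px = 250, upper_arm_px = 180,
                            forearm_px = 160,
                            noise_px = 0, dropout_prob = 0,
                            image_width_px = 1920, image_height_px = 1080,
                            seed = NULL,
                            registry = default_task_registry()) {
  task <- registry[[as.character(task_id)]]
  if (is.null(task)) stop("unknown task_id: ", task_id, call. = FALSE)
  peak_angles_deg <- rep_len(peak_angles_deg, n_reps)
  elbow_min_deg <- rep_len(elbow_min_deg, n_reps)
  stopifnot(fps > 0, rest_s >= 0, n_reps >= 1, bump_duration_s > 0,
            trunk_px > 0, upper_arm_px > 0, forearm_px > 0,
            noise_px >= 0, dropout_prob >= 0, dropout_prob <= 1)
  if (any(peak_angles_deg <= 0 | peak_angles_deg >= 180)) {
    stop("peak angles must lie in (0, 180)", call. = FALSE)
  }
  if (any(elbow_min_deg <= 0 | elbow_min_deg >= 180)) {
    stop("elbow minima must lie in (0, 180)", call. = FALSE)
  }
  structure(list(task_id = task$task_id, task = task,
                 side = match.arg(side, c("left", "right")), fps = fps,
                 rest_s = rest_s, n_reps = n_reps,
                 peak_angles_deg = peak_angles_deg,
                 elbow_min_deg = elbow_min_deg,
                 bump_duration_s = bump_duration_s,
                 baseline_shoulder_deg = baseline_shoulder_deg,
                 baseline_elbow_deg = baseline_elbow_deg,
                 trunk_px = trunk_px, upper_arm_px = upper_arm_px,
                 forearm_px = forearm_px,
                 noise_px = noise_px, dropout_prob = dropout_prob,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px, seed = seed),
            class = "trajectory_spec")
}

# Raised-cosine profile: baseline outside bumps; within bump r the value
# moves from `base` to `peak[r]` and back, reaching peak[r] exactly at the
# bump midpoint.
.bump_profile <- function(t, base, peaks, rest_s, bump_s, n_reps) {
  y <- rep(base, length(t))
  for (r in seq_len(n_reps)) {
    t0 <- rest_s + (r - 1) * (bump_s + rest_s)
    inb <- t >= t0 & t <= t0 + bump_s
    u <- (t[inb] - t0) / bump_s
    y[inb] <- base + (peaks[r] - base) * (1 - cos(2 * pi * u)) / 2
  }
  y
}

.rot <- function(v, ang_deg) {
  a <- ang_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Simulate a task recording with known angle ground truth
#'
#' Places a planar kinematic chain frame by frame: the hip is fixed, the
#' shoulder sits `trunk_px` above it, the elbow is placed at the prescribed
#' shoulder angle from the trunk vector, and the wrist at the prescribed
#' elbow angle from the upper-arm vector. Angle profiles are raised-cosine
#' bumps from the baseline to per-repetition peaks separated by rest
#' periods; the elbow stays at its baseline (near extension) for tasks that
#' do not measure it. Gaussian pixel noise and visibility dropout are
#' applied after exact placement, so the returned ground-truth series are
#' exact. The contralateral arm is present and static (required-landmark
#' completeness) and the whole chain is auto-rescaled with a warning if it
#' would leave the frame.
#'
#' @param spec A [trajectory_spec()].
#' @return List with elements `sequence` (a [landmark_sequence()]) and
#'   `truth`: a named list of exact [joint_angle_series()], one per joint
#'   the task measures (always including `shoulder`).
#' @export
simulate_task_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  duration <- spec$n_reps * spec$bump_duration_s +
    (spec$n_reps + 1) * spec$rest_s
  nf <- round(duration * spec$fps)
  t <- (seq_len(nf) - 1) / spec$fps
  frames <- seq_len(nf) - 1L

  measures_elbow <- "elbow" %in% spec$task$joints_measured
  theta_s <- .bump_profile(t, spec$baseline_shoulder_deg,
                           spec$peak_angles_deg, spec$rest_s,
                           spec$bump_duration_s, spec$n_reps)
  theta_e <- if (measures_elbow) {
    # elbow flexes (angle dips) in time with the shoulder bumps
    -.bump_profile(t, -spec$baseline_elbow_deg, -spec$elbow_min_deg,
                   spec$rest_s, spec$bump_duration_s, spec$n_reps)
  } else {
    rep(spec$baseline_elbow_deg, nf)
  }

  sgn <- if (spec$side == "right") 1 else -1
  W <- spec$image_width_px; H <- spec$image_height_px
  lens <- c(spec$trunk_px, spec$upper_arm_px, spec$forearm_px)
  hip <- c(0.45 * W, 0.72 * H)
  reach <- sum(lens[2:3])
  # auto-rescale if the chain could leave the frame
  max_y <- hip[2]; min_y <- hip[2] - lens[1] - reach
  max_x <- hip[1] + reach; min_x <- hip[1] - reach
  if (min_y < 0 || max_x > W || min_x < 0) {
    scale <- 0.95 * min(hip[2] / (lens[1] + reach),
                        (W - hip[1]) / reach, hip[1] / reach)
    warning("kinematic chain exceeds frame bounds; segment lengths rescaled by ",
            signif(scale, 3))
    lens <- lens * scale
  }

  shoulder <- c(hip[1], hip[2] - lens[1])
  place <- function(ts_deg, te_deg) {
    # trunk ray (shoulder -> hip) points straight down: (0, 1)
    ua_dir <- c(sgn * sin(ts_deg * pi / 180), cos(ts_deg * pi / 180))
    elbow <- shoulder + lens[2] * ua_dir
    wrist <- elbow + lens[3] * .rot(-ua_dir, sgn * te_deg)
    list(elbow = elbow, wrist = wrist)
  }

  side <- spec$side
  other <- if (side == "right") "left" else "right"
  off <- c(-sgn * 80, 0)                       # contralateral x offset
  hip2 <- hip + off
  shoulder2 <- shoulder + off
  ua2 <- c(-sgn * sin(3 * pi / 180), cos(3 * pi / 180))
  elbow2 <- shoulder2 + lens[2] * ua2
  wrist2 <- elbow2 + lens[3] * .rot(-ua2, -sgn * spec$baseline_elbow_deg)

  pts <- lapply(seq_len(nf), function(i) {
    p <- place(theta_s[i], theta_e[i])
    data.frame(
      frame = frames[i], time_s = t[i],
      landmark = c(paste0(side, c("_hip", "_shoulder", "_elbow", "_wrist")),
                   paste0(other, c("_hip", "_shoulder", "_elbow", "_wrist"))),
      x = c(hip[1], shoulder[1], p$elbow[1], p$wrist[1],
            hip2[1], shoulder2[1], elbow2[1], wrist2[1]),
      y = c(hip[2], shoulder[2], p$elbow[2], p$wrist[2],
            hip2[2], shoulder2[2], elbow2[2], wrist2[2]),
      visibility = 1,
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, pts)

  if (spec$noise_px > 0) {
    d$x <- d$x + stats::rnorm(nrow(d), 0, spec$noise_px)
    d$y <- d$y + stats::rnorm(nrow(d), 0, spec$noise_px)
  }
  if (spec$dropout_prob > 0) {
    drop <- stats::runif(nrow(d)) < spec$dropout_prob
    d$visibility[drop] <- 0
  }

  meta <- list(task = spec$task_id, side = side, setting = "lab",
               generator = "simulate_task_trajectory")
  if (!is.null(spec$seed)) meta$seed <- spec$seed
  sequence <- landmark_sequence(d, fps = spec$fps,
                                image_width_px = W, image_height_px = H,
                                metadata = meta)

  mk_truth <- function(vals, joint) {
    joint_angle_series(
      data.frame(frame = frames, time_s = t, angle_deg = vals,
                 valid = TRUE, interpolated = FALSE),
      joint = joint, side = side, fps = spec$fps, metadata = meta)
  }
  truth <- list(shoulder = mk_truth(theta_s, "shoulder"))
  if (measures_elbow) truth$elbow <- mk_truth(theta_e, "elbow")

  list(sequence = sequence, truth = truth)
}

#' Simulate paired measurements from two tools with known agreement
#'
#' Tool 1 reports the truth; tool 2 reports the truth minus `bias_deg` plus
#' Gaussian noise, so the population mean of (tool1 - tool2) equals
#' `bias_deg` and the population limits of agreement are
#' `bias_deg +/- 1.96 * diff_sd_deg`.
#'
#' @param n Number of paired observations (>= 3).
#' @param truth_mean_deg,truth_sd_deg Moments of the underlying true angles.
#' @param bias_deg Systematic difference tool1 - tool2.
#' @param diff_sd_deg SD of the differences.
#' @param seed Optional integer seed (recorded as an attribute).
#' @return Data frame of class `paired_measurements` with columns `tool1`,
#'   `tool2`.
#' @export
simulate_rater_pairs <- function(n, truth_mean_deg = 90, truth_sd_deg = 20,
                                 bias_deg = 0, diff_sd_deg = 2,
                                 seed = NULL) {
  stopifnot(n >= 3, truth_sd_deg >= 0, diff_sd_deg >= 0)
  if (!is.null(seed)) set.seed(seed)
  truth <- stats::rnorm(n, truth_mean_deg, truth_sd_deg)
  m2 <- truth - bias_deg + stats::rnorm(n, 0, diff_sd_deg)
  structure(data.frame(tool1 = truth, tool2 = m2),
            spec = list(n = n, truth_mean_deg = truth_mean_deg,
                        truth_sd_deg = truth_sd_deg, bias_deg = bias_deg,
                        diff_sd_deg = diff_sd_deg, seed = seed),
            class = c("paired_measurements", "data.frame"))
}

#' Simulate a two-way random-effects measurement matrix
#'
#' `y[i, j] = mu + subject[i] + rater[j] + error[i, j]` with independent
#' Gaussian components, giving population
#' `ICC(2,1) = sigma_s^2 / (sigma_s^2 + sigma_r^2 + sigma_e^2)`
#' (stored in the `population_icc` attribute).
#'
#' @param n_subjects,k_raters Matrix dimensions.
#' @param sigma_subject,sigma_rater,sigma_error Component SDs (>= 0).
#' @param grand_mean Grand mean `mu`.
#' @param seed Optional integer seed.
#' @return `n_subjects x k_raters` numeric matrix.
#' @export
simulate_two_way <- function(n_subjects, k_raters = 2,
                             sigma_subject = 3, sigma_rater = 0.7,
                             sigma_error = 0.7, grand_mean = 0,
                             seed = NULL) {
  stopifnot(n_subjects >= 1, k_raters >= 1,
            sigma_subject >= 0, sigma_rater >= 0, sigma_error >= 0)
  if (!is.null(seed)) set.seed(seed)
  r <- stats::rnorm(n_subjects, 0, sigma_subject)
  c_ <- stats::rnorm(k_raters, 0, sigma_rater)
  e <- matrix(stats::rnorm(n_subjects * k_raters, 0, sigma_error),
              n_subjects, k_raters)
  y <- grand_mean + outer(r, rep(1, k_raters)) +
    outer(rep(1, n_subjects), c_) + e
  attr(y, "population_icc") <- sigma_subject^2 /
    (sigma_subject^2 + sigma_rater^2 + sigma_error^2)
  attr(y, "seed") <- seed
  y
}

#' Simulate a full multi-task agreement dataset in long format
#'
#' Builds the long paired-measurement table [agreement_report()] consumes:
#' for every side x task x measured joint, each participant contributes
#' `n_reps` repetitions measured by both tools, with tool 2 offset by
#' `bias_deg` plus Gaussian disagreement noise.
#'
#' @param n_participants Number of participants.
#' @param n_reps Repetitions per participant and task.
#' @param sides Character vector of sides to include.
#' @param setting `"lab"` or `"home"`.
#' @param registry Task registry.
#' @param truth_mean_deg,truth_sd_deg Between-observation angle moments.
#' @param bias_deg,diff_sd_deg Between-tool bias and disagreement SD.
#' @param seed Optional integer seed.
#' @return Long data frame with columns `participant`, `setting`, `task`,
#'   `joint`, `side`, `rep`, `tool`, `angle_deg`.
#' @export
simulate_agreement_dataset <- function(n_participants = 27, n_reps = 3,
                                       sides = c("left", "right"),
                                       setting = "lab",
                                       registry = default_task_registry(),
                                       truth_mean_deg = 90,
                                       truth_sd_deg = 20,
                                       bias_deg = 0, diff_sd_deg = 1.5,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (side in sides) {
    for (task in registry) {
      for (joint in task$joints_measured) {
        n <- n_participants * n_reps
        truth <- stats::rnorm(n, truth_mean_deg, truth_sd_deg)
        m2 <- truth - bias_deg + stats::rnorm(n, 0, diff_sd_deg)
        lab <- expand.grid(rep = seq_len(n_reps),
                           participant = seq_len(n_participants))
        out[[length(out) + 1]] <- data.frame(
          participant = rep(lab$participant, 2),
          setting = setting, task = task$task_id, joint = joint,
          side = side, rep = rep(lab$rep, 2),
          tool = rep(c("tool1", "tool2"), each = n),
          angle_deg = c(truth, m2), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
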