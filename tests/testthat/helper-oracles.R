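# Independent oracles and fixture builders shared across tests.

# ICC(2,1) via stats::aov -- an independent route to the two-way mean
# squares (the package computes them by explicit marginal-mean sums).
icc21_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.numeric(m),
                   s = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ s + r, data = df))[[1]]
  rn <- trimws(rownames(a))
  msr <- a[rn == "s", "Mean Sq"]
  msc <- a[rn == "r", "Mean Sq"]
  mse <- a[rn == "Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Bland-Altman moments and proportional-bias slope from first principles
# (explicit sums; no sd/var/lm).
ba_sums_oracle <- function(m1, m2) {
  n <- length(m1)
  d <- m1 - m2
  bias <- sum(d) / n
  sd_diff <- sqrt(sum((d - bias)^2) / (n - 1))
  a <- (m1 + m2) / 2
  am <- sum(a) / n
  slope <- sum((a - am) * (d - bias)) / sum((a - am)^2)
  list(bias = bias, sd_diff = sd_diff, slope = slope)
}

# Minimal valid landmark frame set: every required landmark at the given
# coordinates (constant pose), n frames at the given fps.
constant_pose_data <- function(n_frames, fps = 30,
                               coords = NULL) {
  lms <- required_landmarks()
  if (is.null(coords)) {
    coords <- data.frame(
      landmark = lms,
      x = c(800, 900, 780, 920, 760, 940, 770, 950),
      y = c(700, 700, 450, 450, 560, 560, 650, 650))
  }
  do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
    data.frame(frame = f, time_s = f / fps, landmark = coords$landmark,
               x = coords$x, y = coords$y, visibility = 1,
               stringsAsFactors = FALSE)
  }))
}

# A sequence placing one side's hip/shoulder/elbow/wrist at explicit points
# over n frames; other side gets a far-away static pose.
posed_sequence <- function(shoulder, elbow, wrist, hip = c(900, 700),
                           side = "right", n_frames = 1, fps = 30) {
  other <- if (side == "right") "left" else "right"
  build <- function(f) {
    data.frame(
      frame = f, time_s = f / fps,
      landmark = c(paste0(side, c("_hip", "_shoulder", "_elbow", "_wrist")),
                   paste0(other, c("_hip", "_shoulder", "_elbow", "_wrist"))),
      x = c(hip[1], shoulder[1], elbow[1], wrist[1], 100, 100, 100, 100),
      y = c(hip[2], shoulder[2], elbow[2], wrist[2], 700, 450, 560, 650),
      visibility = 1, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, lapply(seq_len(n_frames) - 1L, build))
  landmark_sequence(d, fps = fps)
}

# Hand-built angle series from a numeric vector (all valid unless masked).
series_from_values <- function(x, fps = 30, joint = "shoulder",
                               side = "right", valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  joint_angle_series(
    data.frame(frame = seq_along(x) - 1L, time_s = (seq_along(x) - 1) / fps,
               angle_deg = ifelse(valid, x, NA_real_), valid = valid,
               interpolated = FALSE),
    joint = joint, side = side, fps = fps)
}

# Random similarity transform applied to an n x 2 point matrix.
similarity_transform <- function(pts, angle, scale, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  t(scale * R %*% t(pts)) + matrix(shift, nrow(pts), 2, byrow = TRUE)
}
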