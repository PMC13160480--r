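# Interior joint angle and per-frame angle series.
#
# The angle at vertex B between rays B->A and B->C is
#   theta = arccos( ((A-B) . (C-B)) / (|A-B| |C-B|) )
# reported in degrees in [0, 180]. It is invariant to common translation,
# rotation and uniform scaling of (A, B, C), but NOT to scaling x and y by
# different factors -- hence the pixel-space requirement upstream.

# Tolerated floating-point overshoot of |cos| beyond 1. Larger overshoot
# indicates corrupted input and raises.
COS_CLAMP_TOL <- 1e-9

#' Interior angle at a vertex between two rays
#'
#' Computes the interior angle at vertex `b` between rays `b -> a` and
#' `b -> c`, in degrees in `[0, 180]`. The cosine is clamped to `[-1, 1]`
#' to absorb floating-point overshoot for near-collinear triples; an
#' overshoot beyond `1e-9` raises, since it indicates corrupted input.
#'
#' @param a,b,c Length-2 numeric vectors `(x, y)`, or n x 2 matrices for a
#'   vectorized call. `b` is the vertex.
#' @return Angle(s) in degrees in `[0, 180]`.
#' @examples
#' joint_angle(c(0, 1), c(0, 0), c(1, 0))   # 90
#' joint_angle(c(0, 1), c(0, 0), c(0, -1))  # 180
#' @export
joint_angle <- function(a, b, c) {
  a <- .as_xy(a); b <- .as_xy(b); c <- .as_xy(c)
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  if (any(nu == 0 | nv == 0, na.rm = TRUE)) {
    stop("degenerate geometry: zero-length ray (A = B or C = B)", call. = FALSE)
  }
  cosang <- rowSums(u * v) / (nu * nv)
  over <- abs(cosang) > 1 + COS_CLAMP_TOL
  if (any(over, na.rm = TRUE)) {
    stop("corrupted input: |cos(angle)| exceeds 1 beyond tolerance", call. = FALSE)
  }
  cosang <- pmin(1, pmax(-1, cosang))
  deg <- acos(cosang) * 180 / pi
  if (length(deg) == 1) as.numeric(deg) else deg
}

.as_xy <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2) stop("points must have 2 columns (x, y)", call. = FALSE)
    p
  } else {
    if (length(p) != 2) stop("a point must be length-2 (x, y)", call. = FALSE)
    matrix(p, ncol = 2)
  }
}

# Build a joint_angle_series from three landmark tracks.
# valid = all three landmarks at/above the visibility threshold and the
# geometry non-degenerate. Angles are computed wherever coordinates permit,
# including below-threshold frames (they are flagged, not dropped).
.angle_series <- function(seq, name_a, name_b, name_c, joint, side,
                          visibility_threshold = 0.5) {
  validate_landmark_sequence(seq)
  if (isTRUE(attr(seq, "normalized"))) {
    stop("sequence has normalized coordinates; apply normalize_to_pixels() ",
         "before computing joint angles", call. = FALSE)
  }
  present <- unique(seq$data$landmark)
  missing <- setdiff(c(name_a, name_b, name_c), present)
  if (length(missing) > 0) {
    stop("configuration error: landmark(s) not in topology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ta <- landmark_track(seq, name_a)
  tb <- landmark_track(seq, name_b)
  tc <- landmark_track(seq, name_c)

  A <- cbind(ta$x, ta$y); B <- cbind(tb$x, tb$y); C <- cbind(tc$x, tc$y)
  u <- A - B; v <- C - B
  nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
  cosang <- rowSums(u * v) / (nu * nv)
  cosang[!is.na(cosang) & abs(cosang) > 1 + COS_CLAMP_TOL] <- NA
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi

  vis_ok <- ta$visibility >= visibility_threshold &
    tb$visibility >= visibility_threshold &
    tc$visibility >= visibility_threshold
  valid <- vis_ok & is.finite(angle)
  angle[!is.finite(angle)] <- NA_real_

  samples <- data.frame(
    frame = tb$frame,
    time_s = tb$time_s,
    angle_deg = angle,
    valid = valid,
    interpolated = FALSE
  )
  joint_angle_series(samples, joint = joint, side = side, fps = seq$fps,
                     landmarks = c(name_a, name_b, name_c),
                     metadata = seq$metadata)
}

#' Construct a joint-angle time series
#'
#' Container for a per-frame joint angle for one joint and side. Valid
#' samples carry an angle in `[0, 180]` degrees; invalid samples carry `NA`.
#'
#' @param samples Data frame with columns `frame`, `time_s`, `angle_deg`,
#'   `valid`, `interpolated`.
#' @param joint `"shoulder"` or `"elbow"`.
#' @param side `"left"` or `"right"`.
#' @param fps Frame rate of the source sequence.
#' @param landmarks Names of the contributing landmarks `(A, vertex, C)`.
#' @param metadata Source metadata list.
#' @return Object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(samples, joint, side, fps,
                               landmarks = character(), metadata = list()) {
  stopifnot(is.data.frame(samples),
            all(c("frame", "time_s", "angle_deg", "valid", "interpolated")
                %in% names(samples)))
  ok <- samples$valid & !is.na(samples$angle_deg)
  if (any(samples$angle_deg[ok] < 0 | samples$angle_deg[ok] > 180)) {
    stop("invariant violated: angle_deg outside [0, 180] on a valid sample",
         call. = FALSE)
  }
  structure(
    list(samples = samples, joint = joint, side = side, fps = fps,
         landmarks = landmarks, metadata = metadata),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  s <- x$samples
  cat("<joint_angle_series> ", x$side, " ", x$joint, "\n", sep = "")
  cat("  frames:", nrow(s),
      " valid:", sum(s$valid),
      " interpolated:", sum(s$interpolated), "\n")
  if (any(s$valid)) {
    cat("  angle range: [", round(min(s$angle_deg[s$valid]), 2), ", ",
        round(max(s$angle_deg[s$valid]), 2), "] deg\n", sep = "")
  }
  invisible(x)
}

#' Shoulder angle series
#'
#' Per-frame shoulder angle: vertex at the ipsilateral shoulder, rays to the
#' ipsilateral hip (trunk segment) and elbow (upper-arm segment). With the
#' arm hanging parallel to the trunk the angle is ~0 degrees; elevation or
#' abduction raises it toward 180.
#'
#' @param seq A pixel-space [landmark_sequence()].
#' @param side A [side_spec()] or `"left"`/`"right"`.
#' @param visibility_threshold Frames with any contributing landmark below
#'   this visibility are flagged invalid (default 0.5).
#' @return A [joint_angle_series()].
#' @export
shoulder_angle_series <- function(seq, side, visibility_threshold = 0.5) {
  ss <- if (inherits(side, "side_spec")) side else side_spec(side)
  .angle_series(seq, ss$hip, ss$shoulder, ss$elbow,
                joint = "shoulder", side = ss$side,
                visibility_threshold = visibility_threshold)
}

#' Elbow angle series
#'
#' Per-frame elbow angle: vertex at the ipsilateral elbow, rays to the
#' shoulder (upper-arm segment) and wrist (forearm segment). 180 degrees
#' denotes full extension; flexion lowers the angle.
#'
#' @inheritParams shoulder_angle_series
#' @return A [joint_angle_series()].
#' @export
elbow_angle_series <- function(seq, side, visibility_threshold = 0.5) {
  ss <- if (inherits(side, "side_spec")) side else side_spec(side)
  .angle_series(seq, ss$shoulder, ss$elbow, ss$wrist,
                joint = "elbow", side = ss$side,
                visibility_threshold = visibility_threshold)
}

#' Gate an angle series by landmark visibility and bridge short dropouts
#'
#' Re-evaluates sample validity against a visibility threshold on the
#' contributing landmarks, then linearly interpolates interior gaps of at
#' most `max_gap_frames` invalid samples between two valid neighbours;
#' interpolated samples are flagged `interpolated`. Longer gaps stay
#' invalid. Samples are never dropped.
#'
#' @param series A [joint_angle_series()].
#' @param seq The source [landmark_sequence()].
#' @param threshold Visibility threshold in `[0, 1]` (default 0.5).
#' @param max_gap_frames Longest gap bridged by interpolation (default 5).
#' @return A gated `joint_angle_series`.
#' @export
gate_by_visibility <- function(series, seq, threshold = 0.5,
                               max_gap_frames = 5) {
  stopifnot(inherits(series, "joint_angle_series"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  s <- series$samples
  vis <- rep(TRUE, nrow(s))
  for (nm in series$landmarks) {
    tr <- landmark_track(seq, nm)
    vis <- vis & tr$visibility[match(s$frame, tr$frame)] >= threshold
  }
  valid <- vis & !is.na(s$angle_deg)
  angle <- ifelse(valid, s$angle_deg, NA_real_)
  interp <- rep(FALSE, length(angle))

  # bridge interior gaps of <= max_gap_frames
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in seq_along(runs$values)) {
    if (runs$values[r]) next
    if (r == 1 || r == length(runs$values)) next   # boundary gaps stay invalid
    if (runs$lengths[r] > max_gap_frames) next
    i0 <- starts[r] - 1; i1 <- ends[r] + 1
    idx <- starts[r]:ends[r]
    w <- (idx - i0) / (i1 - i0)
    angle[idx] <- (1 - w) * angle[i0] + w * angle[i1]
    valid[idx] <- TRUE
    interp[idx] <- TRUE
  }
  s$angle_deg <- angle
  s$valid <- valid
  s$interpolated <- interp
  out <- series
  out$samples <- s
  out
}

#' Smooth an angle series with a centered moving average
#'
#' Averages over valid samples only, inside a centered window of odd length.
#' `window = 1` is the identity (smoothing disabled). Invalid samples remain
#' invalid and do not contribute.
#'
#' @param series A [joint_angle_series()].
#' @param window Odd positive integer window length (default 5).
#' @return A smoothed `joint_angle_series`.
#' @export
smooth_series <- function(series, window = 5) {
  stopifnot(inherits(series, "joint_angle_series"))
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window == 1) return(series)
  s <- series$samples
  x <- ifelse(s$valid, s$angle_deg, NA_real_)
  h <- (window - 1) / 2
  n <- length(x)
  xs <- c(rep(NA_real_, h), x, rep(NA_real_, h))
  mat <- vapply(seq_len(window), function(j) xs[j:(j + n - 1)], numeric(n))
  if (n == 1) mat <- matrix(mat, nrow = 1)
  sm <- rowMeans(mat, na.rm = TRUE)
  sm[!s$valid] <- NA_real_
  s$angle_deg <- sm
  out <- series
  out$samples <- s
  out
}

# ---- angle-series CSV -----------------------------------------------------

ANGLE_CSV_HEADER <- c("frame", "time_s", "joint", "side", "angle_deg",
                      "valid", "interpolated")

#' Write one or more angle series to CSV
#'
#' Dialect: header `frame,time_s,joint,side,angle_deg,valid,interpolated`;
#' angles in degrees with 4 decimal places; invalid samples carry `NA`.
#' Optional `# key=value` metadata comments (fps is always written).
#'
#' @param series A [joint_angle_series()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(series, path) {
  if (inherits(series, "joint_angle_series")) series <- list(series)
  fps <- series[[1]]$fps
  hdr <- sprintf("# fps=%.17g", fps)
  meta <- series[[1]]$metadata
  for (k in names(meta)) hdr <- c(hdr, sprintf("# %s=%s", k, as.character(meta[[k]])))
  rows <- unlist(lapply(series, function(sr) {
    s <- sr$samples
    sprintf("%d,%.17g,%s,%s,%s,%s,%s",
            s$frame, s$time_s, sr$joint, sr$side,
            ifelse(is.na(s$angle_deg), "NA", sprintf("%.4f", s$angle_deg)),
            ifelse(s$valid, "true", "false"),
            ifelse(s$interpolated, "true", "false"))
  }))
  writeLines(c(hdr, paste(ANGLE_CSV_HEADER, collapse = ","), rows), path)
  invisible(path)
}

#' Read angle series from CSV
#'
#' Inverse of [write_angle_csv()]; returns a list of [joint_angle_series()],
#' one per joint x side present in the file.
#'
#' @param path Path to an angle CSV.
#' @return Named list of `joint_angle_series` (names like `"shoulder_right"`).
#' @export
read_angle_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  n_head <- 0L
  while (n_head < length(lines) && grepl("^#", lines[n_head + 1L])) n_head <- n_head + 1L
  meta <- .parse_meta_comments(lines[seq_len(n_head)])
  d <- utils::read.csv(text = paste(lines[(n_head + 1L):length(lines)],
                                    collapse = "\n"),
                       stringsAsFactors = FALSE)
  if (!identical(names(d), ANGLE_CSV_HEADER)) {
    stop("malformed angle CSV header", call. = FALSE)
  }
  fps <- if (!is.null(meta$fps)) as.numeric(meta$fps) else 30
  meta$fps <- NULL
  keys <- unique(d[, c("joint", "side")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- d[d$joint == keys$joint[i] & d$side == keys$side[i], , drop = FALSE]
    samples <- data.frame(
      frame = as.integer(sub$frame), time_s = sub$time_s,
      angle_deg = as.numeric(sub$angle_deg),
      valid = sub$valid %in% c("true", "TRUE", TRUE),
      interpolated = sub$interpolated %in% c("true", "TRUE", TRUE)
    )
    out[[paste(keys$joint[i], keys$side[i], sep = "_")]] <-
      joint_angle_series(samples, joint = keys$joint[i], side = keys$side[i],
                         fps = fps, metadata = meta)
  }
  out
}
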