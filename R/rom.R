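# Repetition segmentation and functional ROM extraction.
#
# Protocol assumed by the defaults: each recording holds one task repeated
# 3 times with ~10 s of rest between repetitions. Peaks are found on the
# (gated, smoothed) angle trace by topographic prominence; for joints whose
# functional extremum is a minimum (elbow flexion) the trace is negated.

#' Define a clinical task
#'
#' @param task_id Integer task identifier (1-4 in the default registry).
#' @param name Human-readable task name.
#' @param joints_measured Subset of `c("shoulder", "elbow")`.
#' @param expected_repetitions Repetitions per recording (default 3).
#' @param extremum Named list giving, per measured joint, whether the
#'   functional extremum is `"max"` (shoulder elevation/abduction) or
#'   `"min"` (elbow flexion: smaller interior angle = deeper flexion).
#' @return Object of class `task_definition`.
#' @export
task_definition <- function(task_id, name, joints_measured,
                            expected_repetitions = 3,
                            extremum = list(shoulder = "max", elbow = "min")) {
  joints_measured <- match.arg(joints_measured, c("shoulder", "elbow"),
                               several.ok = TRUE)
  stopifnot(expected_repetitions >= 1)
  for (j in joints_measured) {
    if (!identical(extremum[[j]], "max") && !identical(extremum[[j]], "min")) {
      stop("extremum for joint '", j, "' must be \"max\" or \"min\"",
           call. = FALSE)
    }
  }
  structure(list(task_id = as.integer(task_id), name = name,
                 joints_measured = joints_measured,
                 expected_repetitions = as.integer(expected_repetitions),
                 extremum = extremum),
            class = "task_definition")
}

#' Default task registry
#'
#' Four functional upper-limb tasks. Task 1 measures the shoulder only;
#' tasks 2-4 measure shoulder and elbow. The task-id-to-movement mapping is
#' configurable: pass your own list of [task_definition()] wherever a
#' registry is accepted.
#'
#' @return Named list of `task_definition` keyed by task id.
#' @export
default_task_registry <- function() {
  list(
    "1" = task_definition(1, "arm abduction", "shoulder"),
    "2" = task_definition(2, "forward reaching (shoulder elevation)",
                          c("shoulder", "elbow")),
    "3" = task_definition(3, "hand to mouth", c("shoulder", "elbow")),
    "4" = task_definition(4, "hand to head", c("shoulder", "elbow"))
  )
}

#' Analysis configuration for the ROM pipeline
#'
#' Bundles the tunable parameters of the angle-to-ROM pipeline with their
#' defaults: visibility threshold 0.5 (midpoint of the backend confidence
#' scale), gap bridging up to 5 frames, smoothing window 5 frames,
#' peak prominence 10 degrees, peak separation 5 s (half the nominal 10 s
#' rest), and `mode = "peak"` (maximal functional angle; `"excursion"`
#' reports |extremum - baseline| instead).
#'
#' @param visibility_threshold Visibility gate in `[0, 1]`.
#' @param max_gap_frames Longest dropout bridged by interpolation.
#' @param smooth_window Odd moving-average window; 1 disables smoothing.
#' @param min_prominence_deg Minimum topographic prominence of a repetition
#'   peak, degrees.
#' @param min_separation_s Minimum time between repetition peaks, seconds.
#' @param mode `"peak"` or `"excursion"`.
#' @return List of class `rom_config`.
#' @export
rom_config <- function(visibility_threshold = 0.5, max_gap_frames = 5,
                       smooth_window = 5, min_prominence_deg = 10,
                       min_separation_s = 5, mode = c("peak", "excursion")) {
  mode <- match.arg(mode)
  stopifnot(visibility_threshold >= 0, visibility_threshold <= 1,
            max_gap_frames >= 0, smooth_window >= 1,
            smooth_window %% 2 == 1, min_prominence_deg >= 0,
            min_separation_s >= 0)
  structure(list(visibility_threshold = visibility_threshold,
                 max_gap_frames = max_gap_frames,
                 smooth_window = smooth_window,
                 min_prominence_deg = min_prominence_deg,
                 min_separation_s = min_separation_s,
                 mode = mode),
            class = "rom_config")
}

# Local maxima of x (NA-tolerant; plateaus yield their midpoint), with
# topographic prominence: height above the higher of the two key saddles
# toward the nearest higher ground on each side.
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  xf <- x
  # interpolate interior NAs for detection only; peaks must sit on real data
  na <- which(is.na(xf))
  if (length(na) > 0 && length(na) < n) {
    ok <- which(!is.na(xf))
    xf[na] <- stats::approx(ok, xf[ok], xout = na, rule = 2)$y
  } else if (length(na) == n) {
    return(integer(0))
  }
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (xf[i] > xf[i - 1L]) {
      j <- i
      while (j < n && xf[j + 1L] == xf[j]) j <- j + 1L  # plateau
      if (j < n && xf[j + 1L] < xf[j]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks[!is.na(x[peaks])]
}

.prominence <- function(x, peaks) {
  xf <- x
  na <- which(is.na(xf))
  if (length(na) > 0) {
    ok <- which(!is.na(xf))
    xf[na] <- stats::approx(ok, xf[ok], xout = na, rule = 2)$y
  }
  vapply(peaks, function(p) {
    h <- xf[p]
    left <- xf[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l) > 0) min(xf[(max(higher_l) + 1):(p - 1)]) else min(left, h)
    right <- xf[(p + 1):length(xf)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r) > 0) min(xf[(p + 1):(p + min(higher_r) - 1)]) else min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Segment an angle series into task repetitions
#'
#' Finds repetition peaks on the valid part of the trace by topographic
#' prominence, enforces a minimum separation between peaks, and cuts
#' segment boundaries at the lowest point between adjacent peaks (series
#' ends for the outermost segments). When fewer than `expected` qualifying
#' peaks exist, the segments found are returned and a count mismatch is
#' flagged via the `"mismatch"` attribute -- a warning, not an error, so
#' imperfect home recordings degrade gracefully.
#'
#' @param series A [joint_angle_series()] (typically gated and smoothed).
#' @param expected Expected number of repetitions (default 3).
#' @param min_prominence_deg Minimum peak prominence in degrees (default 10).
#' @param min_separation_s Minimum peak separation in seconds (default 5).
#' @param direction `"max"` for shoulder-type peaks, `"min"` for elbow
#'   flexion minima.
#' @return Data frame of class `repetition_segments` with columns
#'   `start_frame`, `end_frame`, `peak_frame`, `peak_angle_deg`,
#'   `baseline_angle_deg`, ordered by time; attributes `n_expected`,
#'   `n_found`, `mismatch`.
#' @export
segment_repetitions <- function(series, expected = 3,
                                min_prominence_deg = 10,
                                min_separation_s = 5,
                                direction = c("max", "min")) {
  stopifnot(inherits(series, "joint_angle_series"))
  direction <- match.arg(direction)
  s <- series$samples
  x <- ifelse(s$valid, s$angle_deg, NA_real_)
  sgn <- if (direction == "min") -1 else 1
  xw <- sgn * x

  peaks <- .find_peaks(xw)
  if (length(peaks) > 0) {
    prom <- .prominence(xw, peaks)
    keep <- peaks[prom >= min_prominence_deg]
    prom <- prom[prom >= min_prominence_deg]
    # enforce separation, preferring higher prominence
    if (length(keep) > 1) {
      min_sep <- min_separation_s * series$fps
      ord <- order(prom, decreasing = TRUE)
      chosen <- integer(0)
      for (p in keep[ord]) {
        if (all(abs(p - chosen) >= min_sep)) chosen <- c(chosen, p)
      }
      keep <- sort(chosen)
    }
    if (length(keep) > expected) {
      heights <- xw[keep]
      keep <- sort(keep[order(heights, decreasing = TRUE)[seq_len(expected)]])
    }
    peaks <- keep
  }

  n_found <- length(peaks)
  if (n_found == 0) {
    seg <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      peak_frame = integer(0), peak_angle_deg = numeric(0),
                      baseline_angle_deg = numeric(0))
  } else {
    bounds <- integer(n_found + 1)
    bounds[1] <- 1L
    bounds[n_found + 1] <- nrow(s)
    if (n_found > 1) {
      for (i in seq_len(n_found - 1)) {
        span <- (peaks[i] + 1):(peaks[i + 1] - 1)
        v <- xw[span]
        bounds[i + 1] <- span[which.min(ifelse(is.na(v), Inf, v))]
      }
    }
    seg <- do.call(rbind, lapply(seq_len(n_found), function(i) {
      i0 <- bounds[i]; i1 <- bounds[i + 1]
      idx <- i0:i1
      seg_x <- xw[idx]
      peak_v <- x[peaks[i]]
      seg_min <- min(seg_x, na.rm = TRUE)
      peak_w <- xw[peaks[i]]
      base_mask <- !is.na(seg_x) & seg_x <= seg_min + 0.2 * (peak_w - seg_min)
      base <- sgn * stats::median(seg_x[base_mask])
      data.frame(start_frame = s$frame[i0], end_frame = s$frame[i1],
                 peak_frame = s$frame[peaks[i]],
                 peak_angle_deg = peak_v, baseline_angle_deg = base)
    }))
  }
  structure(seg, class = c("repetition_segments", "data.frame"),
            n_expected = as.integer(expected), n_found = n_found,
            mismatch = n_found != expected, direction = direction)
}

#' Per-repetition functional ROM value
#'
#' `mode = "peak"` returns the extremal angle inside the segment (maximum
#' for shoulder-type movements, minimum interior angle for elbow flexion).
#' `mode = "excursion"` returns the absolute difference between that
#' extremum and the segment's resting baseline (median angle of the rest
#' period preceding the movement).
#'
#' @param segment One row of [segment_repetitions()] output (or a list with
#'   `start_frame`, `end_frame`, `baseline_angle_deg`).
#' @param series The [joint_angle_series()] the segment indexes into.
#' @param mode `"peak"` or `"excursion"`.
#' @param direction `"max"` or `"min"` extremum.
#' @return ROM value in degrees.
#' @export
peak_rom <- function(segment, series, mode = c("peak", "excursion"),
                     direction = c("max", "min")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  s <- series$samples
  idx <- which(s$frame >= segment$start_frame & s$frame <= segment$end_frame)
  if (length(idx) == 0) stop("segment outside series bounds", call. = FALSE)
  vals <- s$angle_deg[idx][s$valid[idx]]
  if (length(vals) == 0) stop("no valid samples in segment", call. = FALSE)
  ext <- if (direction == "max") max(vals) else min(vals)
  if (mode == "peak") ext else abs(ext - segment$baseline_angle_deg)
}

#' Summarize one recording into per-joint ROM
#'
#' Runs the full pipeline for every joint the task measures: angle series ->
#' visibility gating -> smoothing -> repetition segmentation -> per-rep ROM.
#'
#' @param seq A pixel-space [landmark_sequence()].
#' @param task A [task_definition()].
#' @param side A [side_spec()] or `"left"`/`"right"`.
#' @param config A [rom_config()].
#' @param setting `"lab"` or `"home"` (defaults to sequence metadata, else
#'   `"lab"`).
#' @return List of `rom_summary` objects, one per measured joint. Each
#'   holds the segments, per-repetition ROM values `rep_values`, their
#'   arithmetic mean `mean_rom`, and a `warning` flag on repetition-count
#'   mismatch.
#' @export
summarize_recording <- function(seq, task, side, config = rom_config(),
                                setting = NULL) {
  stopifnot(inherits(task, "task_definition"))
  ss <- if (inherits(side, "side_spec")) side else side_spec(side)
  if (is.null(setting)) {
    setting <- if (!is.null(seq$metadata$setting)) seq$metadata$setting else "lab"
  }
  out <- list()
  for (joint in task$joints_measured) {
    series <- if (joint == "shoulder") {
      shoulder_angle_series(seq, ss, config$visibility_threshold)
    } else {
      elbow_angle_series(seq, ss, config$visibility_threshold)
    }
    series <- gate_by_visibility(series, seq, config$visibility_threshold,
                                 config$max_gap_frames)
    series <- smooth_series(series, config$smooth_window)
    dir <- task$extremum[[joint]]
    segs <- segment_repetitions(series, task$expected_repetitions,
                                config$min_prominence_deg,
                                config$min_separation_s, direction = dir)
    rep_values <- if (nrow(segs) > 0) {
      vapply(seq_len(nrow(segs)), function(i)
        peak_rom(segs[i, ], series, mode = config$mode, direction = dir),
        numeric(1))
    } else numeric(0)
    out[[joint]] <- structure(
      list(task_id = task$task_id, task_name = task$name, joint = joint,
           side = ss$side, setting = setting,
           repetitions = segs, rep_values = rep_values,
           mean_rom = if (length(rep_values) > 0) mean(rep_values) else NA_real_,
           n_expected = task$expected_repetitions,
           warning = attr(segs, "mismatch")),
      class = "rom_summary")
  }
  out
}

#' @export
print.rom_summary <- function(x, ...) {
  cat("<rom_summary> task ", x$task_id, " (", x$task_name, "), ",
      x$side, " ", x$joint, ", ", x$setting, "\n", sep = "")
  cat("  repetitions:", length(x$rep_values), "of", x$n_expected,
      if (isTRUE(x$warning)) "[count mismatch]" else "", "\n")
  if (length(x$rep_values) > 0) {
    cat("  rom (deg):", paste(round(x$rep_values, 2), collapse = ", "),
        " mean:", round(x$mean_rom, 2), "\n")
  }
  invisible(x)
}

#' Write ROM summaries to CSV
#'
#' Dialect: `participant,setting,task,joint,side,rep,rom_deg,warnings`;
#' one row per repetition plus a per-summary aggregate row (`rep = "mean"`).
#'
#' @param summaries A `rom_summary` or list of them (nested lists are
#'   flattened).
#' @param path Output path.
#' @param participant Participant identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_rom_csv <- function(summaries, path, participant = "unknown") {
  if (inherits(summaries, "rom_summary")) summaries <- list(summaries)
  summaries <- .flatten_summaries(summaries)
  rows <- character(0)
  for (sm in summaries) {
    wflag <- if (isTRUE(sm$warning)) "rep_count_mismatch" else ""
    if (length(sm$rep_values) > 0) {
      rows <- c(rows, sprintf("%s,%s,%d,%s,%s,%d,%.17g,%s",
                              participant, sm$setting, sm$task_id, sm$joint,
                              sm$side, seq_along(sm$rep_values),
                              sm$rep_values, wflag))
    }
    rows <- c(rows, sprintf("%s,%s,%d,%s,%s,mean,%.17g,%s",
                            participant, sm$setting, sm$task_id, sm$joint,
                            sm$side, sm$mean_rom, wflag))
  }
  writeLines(c("participant,setting,task,joint,side,rep,rom_deg,warnings",
               rows), path)
  invisible(path)
}

.flatten_summaries <- function(x) {
  out <- list()
  for (el in x) {
    if (inherits(el, "rom_summary")) out <- c(out, list(el))
    else out <- c(out, .flatten_summaries(el))
  }
  out
}
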